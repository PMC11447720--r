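# Train/test split constructions for combinatorial HTE reaction tables:
# seeded random ratio splits (with the compound-coverage restriction used
# for very small training fractions), component-out splits, and the
# ligand x halide-triad x additive hold-out family.

split_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hteyield_split_error")
}

new_split_result <- function(train_idx, test_idx, manifest) {
  stopifnot(length(intersect(train_idx, test_idx)) == 0)
  structure(
    list(train_idx = sort(as.integer(train_idx)),
         test_idx = sort(as.integer(test_idx)),
         manifest = manifest),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result:%s> train %d / test %d\n",
              x$manifest$kind, length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

canonicalize_structures <- function(structures) {
  vapply(structures, function(s) graph_from_smiles(s)$canonical_smiles,
         character(1), USE.NAMES = FALSE)
}

# Round-half-up train count; the alternative rules are exposed because
# published per-ratio training sizes are not consistent under a single rule.
train_count <- function(n, ratio_train, rule = c("half_up", "floor", "ceiling")) {
  rule <- match.arg(rule)
  x <- ratio_train / 100 * n
  switch(rule, half_up = floor(x + 0.5), floor = floor(x), ceiling = ceiling(x))
}

#' Random train/test split at a given percentage ratio
#'
#' Splits the reactions uniformly at random into train and test partitions.
#' The train size is `round(ratio[1]/100 * n)` (round-half-up by default);
#' the remainder goes to test, so the partition is exhaustive. With
#' `coverage = TRUE` (intended for extreme ratios such as 1:99) the draw is
#' repeated until every structure occurring in a training reaction also
#' occurs somewhere in the test partition, so the task remains
#' interpolation even for tiny training sets.
#'
#' @param ds A [reaction_dataset()].
#' @param ratio Length-2 positive numeric vector summing to 100
#'   (train, test).
#' @param seed Integer seed; the same seed always reproduces the split.
#' @param coverage Require train-compound coverage by the test partition.
#' @param max_retries Rejection-sampling budget for `coverage`.
#' @param round_rule Rounding rule for the fractional train count.
#' @return A `split_result` with `train_idx`, `test_idx` and a `manifest`.
#' @export
random_split <- function(ds, ratio = c(70, 30), seed = 1L, coverage = FALSE,
                         max_retries = 1000L, round_rule = "half_up") {
  n <- n_reactions(ds)
  if (n == 0) split_error("empty dataset")
  if (length(ratio) != 2 || any(ratio <= 0) || abs(sum(ratio) - 100) > 1e-8) {
    split_error("ratio must be two positive numbers summing to 100")
  }
  n_train <- train_count(n, ratio[1], round_rule)
  if (n_train < 1 || n_train >= n) {
    split_error("ratio %s:%s yields an empty train or test partition for n=%d",
                ratio[1], ratio[2], n)
  }
  draw <- function(s) {
    with_seed(s, sample.int(n, n_train))
  }
  covered <- function(tr) {
    te <- setdiff(seq_len(n), tr)
    for (role in ds$roles) {
      tr_st <- unique(stats::na.omit(ds$table[[role]][tr]))
      te_st <- unique(stats::na.omit(ds$table[[role]][te]))
      if (!all(tr_st %in% te_st)) return(FALSE)
    }
    TRUE
  }
  attempt <- 0L
  repeat {
    tr <- draw(seed + attempt)
    if (!coverage || covered(tr)) break
    attempt <- attempt + 1L
    if (attempt >= max_retries) {
      split_error("coverage restriction unreachable in %d retries", max_retries)
    }
  }
  new_split_result(
    tr, setdiff(seq_len(n), tr),
    list(kind = "random_ratio", ratio = ratio, seed = seed,
         coverage = coverage, retries = attempt,
         n_train = n_train, n_test = n - n_train)
  )
}

#' Component-out split: hold out all reactions containing given structures
#'
#' The test set is every reaction whose `role` component is one of the
#' held-out structures; the training set is everything else, so no held-out
#' structure ever occurs in a training reaction. This is the additive-out /
#' reactant-out / ligand-out extrapolation construction for HTE tables.
#'
#' @param ds A [reaction_dataset()].
#' @param role Role label the hold-out applies to.
#' @param held_out Character vector of structures (SMILES; canonicalized
#'   before matching).
#' @return A `split_result`.
#' @export
component_out_split <- function(ds, role, held_out) {
  if (!role %in% ds$roles) split_error("unknown role '%s'", role)
  held_canon <- canonicalize_structures(held_out)
  missing <- setdiff(held_canon, ds$registry[[role]])
  if (length(missing) > 0) {
    split_error("structure not in dataset under role '%s': %s",
                role, missing[1])
  }
  test_idx <- reactions_with(ds, role, held_canon)
  if (length(test_idx) == 0 || length(test_idx) == n_reactions(ds)) {
    split_error("component-out split yields an empty partition")
  }
  new_split_result(
    setdiff(seq_len(n_reactions(ds)), test_idx), test_idx,
    list(kind = "component_out", role = role, held_out = held_canon)
  )
}

#' Ligand x halide-triad x additive hold-out splits
#'
#' Builds the rigorous extrapolation family for combinatorial C-N coupling
#' tables: the aryl halides are partitioned into same-scaffold triads (the
#' chloride, bromide and iodide of one scaffold), a fixed set of test
#' additives is chosen, and one split is produced per (ligand, triad) pair.
#' Each test set is the full cross of that ligand, the triad halides and
#' the test additives over all bases (restricted to rows present in the
#' dataset); each training set excludes every reaction containing the
#' held-out ligand OR any triad halide OR any test additive. With 4 ligands
#' and 5 triads this yields 20 splits; on a full 15 x 22 x 4 x 3 table each
#' test set has 1 x 3 x 5 x 3 = 45 reactions.
#'
#' @param ds A [reaction_dataset()].
#' @param ligand_role,halide_role,additive_role Role labels.
#' @param triads List of length-3 character vectors of halide SMILES; must
#'   partition the dataset's halide registry.
#' @param test_additives Character vector of additive SMILES held out in
#'   every split.
#' @return Named list of `split_result` objects (`sTest1`, `sTest2`, ...),
#'   ordered ligand-major then triad.
#' @export
stest_splits <- function(ds, ligand_role = "ligand",
                         halide_role = "aryl_halide",
                         additive_role = "additive",
                         triads, test_additives) {
  for (r in c(ligand_role, halide_role, additive_role)) {
    if (!r %in% ds$roles) split_error("unknown role '%s'", r)
  }
  triads_canon <- lapply(triads, canonicalize_structures)
  all_triad <- unlist(triads_canon)
  if (anyDuplicated(all_triad) > 0) {
    split_error("triads overlap: %s", all_triad[duplicated(all_triad)][1])
  }
  registry_halides <- ds$registry[[halide_role]]
  if (!setequal(all_triad, registry_halides)) {
    split_error("triads do not partition the %s registry (%d vs %d structures)",
                halide_role, length(all_triad), length(registry_halides))
  }
  adds_canon <- canonicalize_structures(test_additives)
  missing <- setdiff(adds_canon, ds$registry[[additive_role]])
  if (length(missing) > 0) {
    split_error("test additive not in dataset: %s", missing[1])
  }

  ligands <- ds$registry[[ligand_role]]
  tab <- ds$table
  splits <- list()
  k <- 0L
  for (lig in ligands) {
    for (t in seq_along(triads_canon)) {
      tri <- triads_canon[[t]]
      in_test <- !is.na(tab[[ligand_role]]) & tab[[ligand_role]] == lig &
        tab[[halide_role]] %in% tri & tab[[additive_role]] %in% adds_canon
      in_train <- (is.na(tab[[ligand_role]]) | tab[[ligand_role]] != lig) &
        !(tab[[halide_role]] %in% tri) & !(tab[[additive_role]] %in% adds_canon)
      k <- k + 1L
      splits[[paste0("sTest", k)]] <- new_split_result(
        which(in_train), which(in_test),
        list(kind = "stest", ligand_role = ligand_role,
             halide_role = halide_role, additive_role = additive_role,
             ligand = lig, triad = tri,
             test_additives = adds_canon, index = k)
      )
    }
  }
  splits
}

#' Tidy summary of one or more splits
#'
#' @param splits A `split_result` or list of them.
#' @return Tibble with one row per split: `split`, `kind`, `n_train`,
#'   `n_test`.
#' @export
split_summary <- function(splits) {
  if (inherits(splits, "split_result")) splits <- list(split = splits)
  bind_rows(imap(splits, function(sp, nm) {
    tibble(split = nm, kind = sp$manifest$kind,
           n_train = length(sp$train_idx), n_test = length(sp$test_idx))
  }))
}

# Leakage scan: structures held out by a split's manifest that occur in its
# training rows. Returns character(0) for a clean split.
scan_leakage <- function(ds, sp) {
  m <- sp$manifest
  held <- switch(
    m$kind,
    component_out = stats::setNames(list(m$held_out), m$role),
    stest = stats::setNames(
      list(m$ligand, m$triad, m$test_additives),
      c(m$ligand_role, m$halide_role, m$additive_role)
    ),
    return(character(0))
  )
  leaks <- character(0)
  for (role in names(held)) {
    if (!role %in% ds$roles) next
    tr_st <- unique(stats::na.omit(ds$table[[role]][sp$train_idx]))
    leaks <- c(leaks, intersect(held[[role]], tr_st))
  }
  leaks
}
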