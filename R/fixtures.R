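# Synthetic HTE-shaped reaction tables with a known yield law.
#
# The generator enumerates the full cross of small per-role compound
# vocabularies (real small molecules, so charges, aromatic systems and salt
# pairs all get exercised) and assigns yields from an additive
# component-effect law plus optional pairwise interactions and Gaussian
# noise, clipped to [0, 100]. The law is returned alongside the dataset so
# recovery tests can assert against ground truth.

# Run code with a temporarily-seeded RNG, restoring prior RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Built-in compound vocabularies for synthetic fixtures
#'
#' Small real molecules organised by reaction role: 15 aryl halides (five
#' scaffolds, each as the chloride, bromide and iodide, mirroring the
#' halide-triad structure of combinatorial C-N coupling screens), 22
#' azole-type additives, 4 phosphine ligands, 3 amine bases, and 6
#' organoboron compounds (boronic acids, a pinacol ester and a potassium
#' trifluoroborate salt pair, so charged and multi-fragment inputs are
#' exercised).
#'
#' @return Named list of character vectors of SMILES.
#' @export
fixture_vocabularies <- function() {
  halide_scaffolds <- c(
    "%sc1cccnc1",      # 3-halopyridine
    "%sc1ccccn1",      # 2-halopyridine
    "%sc1ccccc1",      # halobenzene
    "%sc1ccc(C)cc1",   # 4-halotoluene
    "%sc1ccc(OC)cc1"   # 4-haloanisole
  )
  halides <- unlist(lapply(halide_scaffolds, function(sc) {
    vapply(c("Cl", "Br", "I"), function(x) sprintf(sc, x), character(1))
  }))
  additives <- c(
    "c1cnoc1",                    # isoxazole
    "Cc1cnoc1", "CCc1cnoc1", "CCCc1cnoc1", "CC(C)c1cnoc1",
    "COc1cnoc1", "OCc1cnoc1", "Clc1cnoc1", "Brc1cnoc1", "Fc1cnoc1",
    "c1ccc(-c2cnoc2)cc1",         # phenylisoxazole analogue
    "Cc1ccc(-c2cnoc2)cc1", "COc1ccc(-c2cnoc2)cc1", "Fc1ccc(-c2cnoc2)cc1",
    "Cc1onc(C)c1",                # dimethyl positional isomer
    "Cc1noc(C)c1",
    "c1ccc2oncc2c1",              # benzisoxazole analogue
    "c1ccc2conc2c1",
    "Cc1occc1=O",                 # furanone-type carbonyl heterocycle
    "O=C1CCCO1",                  # butyrolactone
    "Cn1cccn1",                   # N-methylpyrazole
    "c1ccn(C)c1"                  # N-methylpyrrole
  )
  ligands <- c(
    "CC(C)(C)P(C(C)(C)C)C(C)(C)C",          # tri-tert-butylphosphine
    "c1ccc(P(c2ccccc2)c2ccccc2)cc1",        # triphenylphosphine
    "CC(C)P(C(C)C)C(C)C",                   # triisopropylphosphine
    "CCCCP(CCCC)CCCC"                       # tri-n-butylphosphine
  )
  bases <- c(
    "CCN(CC)CC",          # triethylamine
    "CCN(C(C)C)C(C)C",    # diisopropylethylamine
    "CN(C)C(=N)N(C)C"     # tetramethylguanidine
  )
  organoboron <- c(
    "Cc1ccc2c(cnn2C2CCCCO2)c1B(O)O",
    "Cc1ccc2c(cnn2C2CCCCO2)c1[B-](F)(F)F.[K+]",
    "Cc1ccc2c(cnn2C2CCCCO2)c1B1OC(C)(C)C(C)(C)O1",
    "OB(O)c1ccccc1",
    "OB(O)c1ccc(C)cc1",
    "OB(O)c1cccnc1"
  )
  list(aryl_halide = halides, additive = additives,
       ligand = ligands, base = bases, organoboron = organoboron)
}

#' Specify a synthetic combinatorial reaction fixture
#'
#' @param roles Named list of per-role SMILES vocabularies (see
#'   [fixture_vocabularies()]). Role order fixes the role vocabulary.
#' @param base_yield Intercept of the yield law, percent.
#' @param effect_sd Standard deviation of the per-compound additive effects
#'   drawn for roles without user-supplied effects.
#' @param effects Optional tibble (`role`, `structure`, `effect`) giving
#'   the additive effect of each compound (structure as the vocabulary
#'   SMILES string). Effects for missing entries are drawn seeded.
#' @param interactions Optional tibble (`role_a`, `structure_a`, `role_b`,
#'   `structure_b`, `delta`) of pairwise interaction offsets applied when
#'   both structures occur in a reaction.
#' @param noise_sd Gaussian noise SD in yield points (default 5).
#' @param drop_fraction Fraction of the full cross to drop at random.
#' @param seed RNG seed controlling effects, noise and dropping.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(roles, base_yield = 50, effect_sd = 10,
                         effects = NULL, interactions = NULL,
                         noise_sd = 5, drop_fraction = 0, seed = 1L) {
  stopifnot(length(roles) > 0, !is.null(names(roles)),
            all(nzchar(names(roles))), noise_sd >= 0,
            drop_fraction >= 0, drop_fraction < 1)
  structure(
    list(roles = roles, base_yield = base_yield, effect_sd = effect_sd,
         effects = effects, interactions = interactions, noise_sd = noise_sd,
         drop_fraction = drop_fraction, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic HTE reaction dataset with known ground truth
#'
#' Enumerates the full combinatorial cross of the role vocabularies (minus
#' an optional random drop fraction), computes
#' `yield = clip(base + sum(effects) + sum(interactions) + noise, 0, 100)`,
#' and returns the dataset together with the realized yield law.
#'
#' @param spec A [fixture_spec()].
#' @return List with `dataset` (a [reaction_dataset()]) and `truth` (list:
#'   `base_yield`, `effects` tibble, `interactions`, `noise_sd`,
#'   `clipped_fraction`, `yield_fun` closure evaluating the noise-free law
#'   on vocabulary SMILES).
#' @examples
#' voc <- fixture_vocabularies()
#' spec <- fixture_spec(list(ligand = voc$ligand[1:2], base = voc$base),
#'                      noise_sd = 0, seed = 7)
#' fx <- generate_fixture(spec)
#' n_reactions(fx$dataset)  # 6
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (role in names(spec$roles)) {
    for (s in spec$roles[[role]]) {
      tryCatch(graph_from_smiles(s), error = function(e) {
        data_error("invalid SMILES '%s' in vocabulary for role '%s'", s, role)
      })
    }
  }
  with_seed(spec$seed, {
    effects <- spec$effects
    if (is.null(effects)) {
      effects <- bind_rows(imap(spec$roles, function(voc, role) {
        tibble(role = role, structure = voc,
               effect = stats::rnorm(length(voc), 0, spec$effect_sd))
      }))
    } else {
      effects <- as_tibble(effects)
    }
    grid <- expand.grid(lapply(spec$roles, seq_along), KEEP.OUT.ATTRS = FALSE)
    names(grid) <- names(spec$roles)
    cols <- lapply(names(spec$roles), function(role) {
      spec$roles[[role]][grid[[role]]]
    })
    names(cols) <- names(spec$roles)
    tab <- as_tibble(cols)

    eff_lookup <- lapply(names(spec$roles), function(role) {
      e <- effects[effects$role == role, ]
      stats::setNames(e$effect, e$structure)
    })
    names(eff_lookup) <- names(spec$roles)
    raw <- rep(spec$base_yield, nrow(tab))
    for (role in names(spec$roles)) {
      ef <- eff_lookup[[role]][tab[[role]]]
      ef[is.na(ef)] <- 0
      raw <- raw + unname(ef)
    }
    if (!is.null(spec$interactions)) {
      ia <- as_tibble(spec$interactions)
      for (k in seq_len(nrow(ia))) {
        hit <- tab[[ia$role_a[k]]] == ia$structure_a[k] &
          tab[[ia$role_b[k]]] == ia$structure_b[k]
        raw[hit] <- raw[hit] + ia$delta[k]
      }
    }
    if (spec$noise_sd > 0) raw <- raw + stats::rnorm(nrow(tab), 0, spec$noise_sd)
    yields <- pmin(100, pmax(0, raw))
    clipped_fraction <- mean(yields != raw)
    tab$yield <- yields

    if (spec$drop_fraction > 0) {
      keep <- sort(sample.int(nrow(tab),
                              round((1 - spec$drop_fraction) * nrow(tab))))
      tab <- tab[keep, , drop = FALSE]
    }

    yield_fun <- local({
      base <- spec$base_yield; el <- eff_lookup; ia <- spec$interactions
      function(components) {
        y <- base
        for (role in names(components)) {
          e <- el[[role]][components[[role]]]
          if (length(e) == 1 && !is.na(e)) y <- y + unname(e)
        }
        if (!is.null(ia)) {
          for (k in seq_len(nrow(ia))) {
            if (identical(components[[ia$role_a[k]]], ia$structure_a[k]) &&
                identical(components[[ia$role_b[k]]], ia$structure_b[k])) {
              y <- y + ia$delta[k]
            }
          }
        }
        min(100, max(0, y))
      }
    })

    list(
      dataset = reaction_dataset(tab, names(spec$roles)),
      truth = list(base_yield = spec$base_yield, effects = effects,
                   interactions = spec$interactions, noise_sd = spec$noise_sd,
                   clipped_fraction = clipped_fraction, yield_fun = yield_fun)
    )
  })
}

#' Generate a synthetic pretraining corpus
#'
#' Assembles random drug-like molecules by decorating aromatic and
#' aliphatic scaffolds with substituents, for exercising the contrastive
#' pretraining path without any external corpus. Heavy-atom counts mostly
#' fall in the 10-30 window used by the corpus filter.
#'
#' @param n Number of molecules.
#' @param seed RNG seed.
#' @return Character vector of SMILES.
#' @export
fixture_corpus <- function(n = 200, seed = 1L) {
  scaffolds <- c(
    "c1ccc(%s)cc1-c1ccc(%s)cc1",      # disubstituted biphenyl
    "c1ccc(C(=O)N(%s)%s)cc1",          # benzamide
    "c1ccc(OC(%s)%s)cc1",              # benzylic ether
    "c1cc(%s)nc(N(C)%s)n1",            # aminopyrimidine
    "c1ccc2c(c1)oc(C(%s)%s)n2",        # benzoxazole
    "C1CCN(C(=O)C(%s)%s)CC1",          # piperidine amide
    "c1ccc2ccc(C(%s)%s)cc2c1"          # naphthalene
  )
  subs <- c("C", "CC", "CCC", "CC(C)C", "OC", "CO", "F", "Cl", "Br",
            "C(=O)OC", "OCC", "CCN(C)C", "c1ccccc1", "C#N",
            "CCO", "C1CCCCC1", "c1ccncc1", "CC(C)(C)C")
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      sprintf(sample(scaffolds, 1), sample(subs, 1), sample(subs, 1))
    }, character(1))
  })
}
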