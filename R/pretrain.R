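# Contrastive pretraining of the message-passing stage: two random
# augmentations of one molecule form a positive pair, all other molecules
# in the batch are negatives, and the normalized-temperature cross-entropy
# (NT-Xent) loss over cosine similarities pulls positives together. Four
# augmentations are available; mini-subgraph removal repeatedly deletes a
# random surviving atom together with its radius-1 neighbors until at
# least ceiling(ratio * n) atoms are gone, keeping deletions strictly
# local so the surviving atoms' wider environment identifiers still carry
# information about the removed parts.

#' Filter a pretraining corpus by heavy-atom count
#'
#' Retains molecules with between 10 and 30 heavy atoms inclusive.
#' Unparsable entries are dropped and counted rather than raised.
#'
#' @param smiles_list Character vector of SMILES.
#' @param min_atoms,max_atoms Inclusive heavy-atom bounds.
#' @return Filtered character vector with attribute `dropped` =
#'   `c(parse = ..., size = ...)`.
#' @export
filter_corpus <- function(smiles_list, min_atoms = 10L, max_atoms = 30L) {
  n_heavy <- vapply(smiles_list, function(s) {
    tryCatch(nrow(parse_smiles(s)$atoms), error = function(e) NA_integer_)
  }, integer(1), USE.NAMES = FALSE)
  parse_drop <- sum(is.na(n_heavy))
  keep <- !is.na(n_heavy) & n_heavy >= min_atoms & n_heavy <= max_atoms
  out <- smiles_list[keep]
  attr(out, "dropped") <- c(parse = parse_drop,
                            size = sum(!keep) - parse_drop)
  out
}

#' Augmentation configuration
#'
#' @param method One of `"atom_masking"`, `"bond_deletion"`,
#'   `"subgraph_removal"`, `"mini_subgraph_removal"`.
#' @param ratio Fraction of atoms (or bonds, for bond deletion) affected,
#'   in (0, 1); the affected count is `ceiling(ratio * n)`.
#' @param seed Integer seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(method = c("mini_subgraph_removal",
                                           "atom_masking", "bond_deletion",
                                           "subgraph_removal"),
                                ratio = 0.25, seed = 1L) {
  method <- match.arg(method)
  stopifnot(ratio > 0, ratio < 1)
  structure(list(method = method, ratio = ratio, seed = as.integer(seed)),
            class = "augmentation_config")
}

aug_error <- function(msg, ...) abort(sprintf(msg, ...),
                                      class = "hteyield_augment_error")

# Rebuild a graph after deleting atoms: reindex bonds, recompute
# environment identifiers on the surviving structure.
delete_atoms <- function(g, del) {
  n <- nrow(g$atoms)
  keep <- setdiff(seq_len(n), del)
  if (length(keep) == 0) aug_error("augmentation would delete the whole graph")
  remap <- match(seq_len(n), keep)
  b <- g$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  out <- g
  out$atoms <- g$atoms[keep, , drop = FALSE]
  out$bonds <- b
  out$env_ids <- compute_env_ids(out, g$id_radius_max %||% 3L)
  out$canonical_smiles <- write_canonical_smiles(out)
  out$deleted <- del
  out
}

# Unseeded core; draws from the current RNG stream.
augment_impl <- function(g, method, ratio) {
  n <- nrow(g$atoms)
  if (n == 0) aug_error("empty graph")
  nb <- neighbor_list(g)
  if (method == "atom_masking") {
    k <- ceiling(ratio * n)
    if (k >= n + 1) aug_error("mask count exceeds graph size")
    sel <- sample.int(n, k)
    out <- g
    out$atoms$masked[sel] <- TRUE
    # identifiers are functions of the untouched topology; masking is a
    # feature-level operation
    return(out)
  }
  if (method == "bond_deletion") {
    m <- nrow(g$bonds)
    if (m == 0) return(g)
    k <- min(m, ceiling(ratio * m))
    sel <- sample.int(m, k)
    out <- g
    out$bonds <- g$bonds[-sel, , drop = FALSE]
    out$env_ids <- compute_env_ids(out, g$id_radius_max %||% 3L)
    out$canonical_smiles <- write_canonical_smiles(out)
    return(out)
  }
  target <- ceiling(ratio * n)
  if (target >= n) aug_error("deletion target %d >= graph size %d", target, n)
  if (method == "subgraph_removal") {
    # grow one connected region of `target` atoms from a random seed atom
    seed_atom <- sample.int(n, 1)
    region <- seed_atom
    frontier <- seed_atom
    while (length(region) < target) {
      cand <- setdiff(unique(unlist(lapply(frontier, function(a) nb[[a]][, 1]))),
                      region)
      if (length(cand) == 0) {
        cand <- setdiff(seq_len(n), region)  # disconnected remainder
        if (length(cand) == 0) break
        cand <- cand[sample.int(length(cand), 1)]
      }
      take <- head(cand[sample.int(length(cand))], target - length(region))
      frontier <- take
      region <- c(region, take)
    }
    return(delete_atoms(g, region))
  }
  if (method == "mini_subgraph_removal") {
    deleted <- integer(0)
    centers <- integer(0)
    surviving <- seq_len(n)
    while (length(deleted) < target) {
      if (length(surviving) == 0) break
      center <- surviving[sample.int(length(surviving), 1)]
      hood <- c(center, intersect(nb[[center]][, 1], surviving))
      # never empty the graph: trim the final neighborhood if needed
      room <- length(surviving) - 1L
      if (length(hood) > room + 1L) hood <- hood[seq_len(room + 1L)]
      if (length(hood) > length(surviving) - 1L) hood <- hood[-length(hood)]
      if (length(hood) == 0) break
      centers <- c(centers, center)
      deleted <- c(deleted, hood)
      surviving <- setdiff(surviving, hood)
    }
    out <- delete_atoms(g, deleted)
    out$centers <- centers
    return(out)
  }
  aug_error("unknown augmentation method '%s'", method)
}

#' Augment a molecular graph
#'
#' Applies one of the four contrastive-learning augmentations. Deletion
#' methods remove atoms (with incident bonds) outright, possibly leaving a
#' disconnected remnant, and recompute environment identifiers on the
#' surviving structure; atom masking flags atoms for the MASK embedding
#' without touching the topology. The same seed always yields the same
#' augmented graph.
#'
#' @param g A `mol_graph`.
#' @param cfg An [augmentation_config()].
#' @return The augmented `mol_graph`; deletion methods attach the original
#'   indices in `$deleted` (and `$centers` for mini-subgraph removal).
#' @export
augment <- function(g, cfg) {
  stopifnot(inherits(cfg, "augmentation_config"))
  with_seed(cfg$seed, augment_impl(g, cfg$method, cfg$ratio))
}

# NT-Xent on the tape: z is 2B x d arranged as B pairs (i, i+B). Cosine
# similarities at temperature tau; self-similarity excluded; loss averaged
# over all 2B anchors.
tp_nt_xent <- function(tape, z, temperature) {
  m <- nrow(node_value(z))
  stopifnot(m %% 2 == 0, m >= 4, temperature > 0)
  B <- m %/% 2L
  zn <- tp_l2_normalize_rows(tape, z)
  sim <- tp_scale(tape, tp_matmul_t(tape, zn, zn), 1 / temperature)
  self_mask <- diag(-1e30, m)
  lse <- tp_logsumexp_rows(tape, sim, mask = self_mask)          # m x 1
  pos_sel <- matrix(0, m, m)
  pos_sel[cbind(seq_len(m), c(B + seq_len(B), seq_len(B)))] <- 1
  pos <- tp_matmul(tape, tp_mul(tape, sim, pos_sel),
                   matrix(1, m, 1))                              # m x 1
  tp_scale(tape, tp_sum(tape, tp_add(tape, lse, tp_scale(tape, pos, -1))),
           1 / m)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' Embeddings are arranged as B positive pairs: rows `1..B` are the first
#' views, rows `B+1..2B` the matching second views. The loss is
#' `-log softmax(sim(i, pair(i)) / tau)` over all other rows, averaged over
#' the `2B` anchors; cosine similarity, self-similarity excluded,
#' symmetric over the two views.
#'
#' @param z Numeric matrix, `2B x d`, `B >= 2`.
#' @param temperature Softmax temperature `tau > 0`.
#' @return Scalar loss.
#' @export
contrastive_loss <- function(z, temperature = 0.1) {
  if (nrow(z) < 4 || nrow(z) %% 2 != 0) {
    abort("need at least 2 pairs (4 embeddings), arranged as B pairs",
          class = "hteyield_loss_error")
  }
  tape <- tape_new()
  tp_nt_xent(tape, tp_const(tape, z), temperature)$value[1, 1]
}

# Molecule embeddings under an MPNN parameter set: summed atom states.
mpnn_embed <- function(cfg, mpnn, vocab, graphs) {
  comps <- lapply(graphs, function(g) list(mol = g))
  b <- assemble_batch(comps, vocab, "mol", NULL)
  tape <- tape_new()
  H <- mpnn_stage(tape, mpnn, cfg, b, training = FALSE)
  dense(b$G %*% H$value)
}

#' Pretrain the message-passing network contrastively
#'
#' For every batch, each molecule is augmented twice independently; the
#' summed MPNN atom states pass through a two-layer projection head and the
#' NT-Xent loss is minimized with Adam. The projection head is discarded;
#' the returned checkpoint holds the MPNN parameters and the identifier
#' vocabulary (built from the unaugmented corpus; identifiers created by
#' deletions map to the trainable UNK row). The transformer encoder and
#' regression head are never pretrained.
#'
#' @param corpus Character vector of SMILES (filtered internally via
#'   [filter_corpus()]; set `filter = FALSE` to skip).
#' @param aug_cfg An [augmentation_config()]; its seed controls the whole
#'   run.
#' @param model_cfg A [model_config()] fixing `d_embed`, `d_hidden`, `L`
#'   and the update rule.
#' @param epochs Training epochs.
#' @param batch_size Molecules per batch (each contributes two views).
#' @param lr Adam learning rate.
#' @param temperature NT-Xent temperature.
#' @param filter Apply the 10-30 heavy-atom corpus filter first.
#' @param quiet Suppress progress lines.
#' @return An `mpnn_checkpoint`: list with `cfg`, `vocab`, `mpnn_values`
#'   (parameter matrices) and `history` (tibble epoch/loss).
#' @export
pretrain_mpnn <- function(corpus, aug_cfg = augmentation_config(),
                          model_cfg = model_config(), epochs = 5L,
                          batch_size = 32L, lr = 1e-3, temperature = 0.1,
                          filter = TRUE, quiet = TRUE) {
  if (filter) corpus <- filter_corpus(corpus)
  if (length(corpus) == 0) {
    abort("corpus empty after filtering", class = "hteyield_data_error")
  }
  with_seed(aug_cfg$seed, {
    graphs <- lapply(corpus, graph_from_smiles)
    vocab <- build_env_vocab(graphs)
    mpnn <- init_mpnn_params(model_cfg, vocab_size(vocab))
    d_h <- model_cfg$d_hidden
    proj <- list(W1 = new_param(init_mat(d_h, d_h)),
                 b1 = new_param(matrix(0, 1, d_h)),
                 W2 = new_param(init_mat(d_h, d_h)))
    params <- flatten_params(list(mpnn, proj))
    n <- length(graphs)
    history <- list()
    step <- 0L
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0; ep_n <- 0L
      for (bi in batches) {
        if (length(bi) < 2) next
        views <- c(
          lapply(graphs[bi], function(g) list(mol = augment_impl(g, aug_cfg$method, aug_cfg$ratio))),
          lapply(graphs[bi], function(g) list(mol = augment_impl(g, aug_cfg$method, aug_cfg$ratio)))
        )
        b <- assemble_batch(views, vocab, "mol", NULL)
        tape <- tape_new()
        H <- mpnn_stage(tape, mpnn, model_cfg, b, training = FALSE)
        Z <- tp_matmul(tape, b$G, H)
        Z <- tp_relu(tape, tp_add(tape, tp_matmul(tape, Z, tp_param(tape, proj$W1)),
                                  tp_param(tape, proj$b1)))
        Z <- tp_matmul(tape, Z, tp_param(tape, proj$W2))
        loss <- tp_nt_xent(tape, Z, temperature)
        zero_grads(params)
        backward(tape, loss)
        step <- step + 1L
        adam_step(params, lr, step)
        ep_loss <- ep_loss + loss$value[1, 1] * length(bi)
        ep_n <- ep_n + length(bi)
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss / ep_n)
      if (!quiet) message(sprintf("pretrain epoch %d  loss %.4f",
                                  epoch, ep_loss / ep_n))
    }
    structure(
      list(cfg = model_cfg[c("d_embed", "d_hidden", "L", "update")],
           vocab = vocab,
           mpnn_values = lapply(mpnn, function(p) p$value),
           history = bind_rows(history)),
      class = "mpnn_checkpoint"
    )
  })
}

#' @export
print.mpnn_checkpoint <- function(x, ...) {
  cat(sprintf("<mpnn_checkpoint> d_embed=%d d_hidden=%d L=%d | vocab %d ids\n",
              x$cfg$d_embed, x$cfg$d_hidden, x$cfg$L, length(x$vocab)))
  invisible(x)
}

#' Molecule embeddings from a pretrained checkpoint
#'
#' @param ckpt An `mpnn_checkpoint`.
#' @param graphs List of `mol_graph` objects.
#' @return Numeric matrix, one row per molecule (summed atom states).
#' @export
embed_molecules <- function(ckpt, graphs) {
  stopifnot(inherits(ckpt, "mpnn_checkpoint"))
  cfg <- model_config(d_embed = ckpt$cfg$d_embed, d_hidden = ckpt$cfg$d_hidden,
                      L = ckpt$cfg$L, update = ckpt$cfg$update)
  mpnn <- lapply(ckpt$mpnn_values, new_param)
  mpnn_embed(cfg, mpnn, ckpt$vocab, graphs)
}

#' Save / load an MPNN checkpoint
#'
#' @param ckpt An `mpnn_checkpoint`.
#' @param path File path (RDS).
#' @return `path` / the checkpoint.
#' @export
write_mpnn_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "mpnn_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname write_mpnn_checkpoint
#' @export
read_mpnn_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "mpnn_checkpoint"))
  ckpt
}
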