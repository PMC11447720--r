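# The yield-prediction architecture: a shared message-passing network over
# each component graph, row-wise concatenation of the component atom
# matrices, additive reaction-role embeddings, N transformer-encoder blocks
# (multihead self-attention + layer normalization, no positional encoding),
# summation readout and an MLP regression head on the percent yield.

#' Model configuration
#'
#' Hyper-parameters of the MPNN-Transformer yield model. The defaults are
#' this package's implementation choices; tests and desk-scale runs use
#' smaller widths via explicit arguments.
#'
#' @param d_embed Atom (environment-identifier) embedding width.
#' @param d_hidden MPNN/encoder hidden width; must be divisible by
#'   `n_heads`.
#' @param L Number of message-passing rounds (`L = 0` returns the input
#'   projection).
#' @param N Number of transformer-encoder blocks.
#' @param n_heads Attention heads.
#' @param d_mlp Hidden widths of the readout MLP.
#' @param dropout Dropout rate applied to MPNN and attention outputs during
#'   training.
#' @param update Atom-state update: `"gru"` (gated recurrent update, shared
#'   across rounds) or `"linear"` (state times a self-weight plus the
#'   aggregated message; useful for closed-form checks).
#' @param yield_scale `"unit"` trains on yield/100 and reports x100;
#'   `"percent"` trains on the raw percent scale.
#' @param lr,batch_size,max_epochs,patience,val_fraction Training controls;
#'   early stopping monitors a seeded validation fraction of the training
#'   data.
#' @param seed Integer seed controlling initialization, batching, dropout
#'   and the validation split.
#' @return A `yield_model_config` list.
#' @export
model_config <- function(d_embed = 128L, d_hidden = 128L, L = 3L, N = 2L,
                         n_heads = 4L, d_mlp = 64L, dropout = 0.1,
                         update = c("gru", "linear"),
                         yield_scale = c("unit", "percent"),
                         lr = 1e-3, batch_size = 32L, max_epochs = 100L,
                         patience = 10L, val_fraction = 0.1, seed = 1L) {
  update <- match.arg(update)
  yield_scale <- match.arg(yield_scale)
  stopifnot(L >= 0, N >= 0, d_hidden %% n_heads == 0, dropout >= 0,
            dropout < 1, val_fraction >= 0, val_fraction < 1)
  structure(
    list(d_embed = as.integer(d_embed), d_hidden = as.integer(d_hidden),
         L = as.integer(L), N = as.integer(N), n_heads = as.integer(n_heads),
         d_mlp = as.integer(d_mlp), dropout = dropout, update = update,
         yield_scale = yield_scale, lr = lr,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "yield_model_config"
  )
}

id_key <- function(ids) sprintf("%.0f", ids)

# Environment-identifier vocabulary: identifier value -> embedding row.
# Reserved rows: UNK (unseen identifiers at inference) and MASK (atom
# masking augmentation).
build_env_vocab <- function(graphs) {
  keys <- unique(unlist(lapply(graphs, function(g) id_key(as.vector(g$env_ids)))))
  stats::setNames(seq_along(keys) + 2L, keys)  # 1 = UNK, 2 = MASK
}

vocab_size <- function(vocab) length(vocab) + 2L

vocab_lookup <- function(vocab, ids) {
  idx <- unname(vocab[id_key(ids)])
  idx[is.na(idx)] <- 1L  # UNK
  idx
}

# Per-structure encoding against a vocabulary: for each atom the vocabulary
# rows of its radius-0..3 identifiers (MASK replaces all four when the atom
# is masked), plus directed edges with bond codes.
structure_encoding <- function(g, vocab) {
  n <- nrow(g$atoms)
  rows <- integer(0); cols <- integer(0)
  for (a in seq_len(n)) {
    if (isTRUE(g$atoms$masked[a])) {
      rows <- c(rows, a); cols <- c(cols, 2L)
    } else {
      vi <- vocab_lookup(vocab, g$env_ids[a, ])
      rows <- c(rows, rep(a, length(vi))); cols <- c(cols, vi)
    }
  }
  b <- g$bonds
  if (nrow(b) > 0) {
    code <- bond_code(b$order, b$aromatic)
    src <- c(b$i, b$j); tgt <- c(b$j, b$i); ec <- c(code, code)
  } else {
    src <- integer(0); tgt <- integer(0); ec <- integer(0)
  }
  list(n_atoms = n, feat_rows = rows, feat_cols = cols,
       edge_src = src, edge_tgt = tgt, edge_code = ec)
}

# Assemble a batch of reactions (lists of role-labelled components) into
# the sparse operators the forward pass needs. `components_list` is a list
# of named lists (role -> mol_graph | mol_absent); roles fixes embedding
# indices.
assemble_batch <- function(components_list, vocab, roles, enc_cache = NULL) {
  V <- vocab_size(vocab)
  n_rxn <- length(components_list)
  feat_r <- list(); feat_c <- list()
  e_src <- list(); e_tgt <- list(); e_code <- list()
  role_row <- list(); rxn_row <- list(); real_row <- list()
  off <- 0L
  for (i in seq_len(n_rxn)) {
    comps <- components_list[[i]]
    for (role in names(comps)) {
      comp <- comps[[role]]
      role_id <- match(role, roles)
      if (is.na(role_id)) data_error("unknown role '%s'", role)
      if (is_absent(comp)) {
        off <- off + 1L
        role_row[[length(role_row) + 1L]] <- stats::setNames(role_id, off)
        rxn_row[[length(rxn_row) + 1L]] <- stats::setNames(i, off)
        real_row[[length(real_row) + 1L]] <- stats::setNames(0, off)
        next
      }
      key <- comp$canonical_smiles
      enc <- if (!is.null(enc_cache) && !is.null(enc_cache[[key]])) {
        enc_cache[[key]]
      } else {
        e <- structure_encoding(comp, vocab)
        if (!is.null(enc_cache)) enc_cache[[key]] <- e
        e
      }
      feat_r[[length(feat_r) + 1L]] <- enc$feat_rows + off
      feat_c[[length(feat_c) + 1L]] <- enc$feat_cols
      e_src[[length(e_src) + 1L]] <- enc$edge_src + off
      e_tgt[[length(e_tgt) + 1L]] <- enc$edge_tgt + off
      e_code[[length(e_code) + 1L]] <- enc$edge_code
      rows <- off + seq_len(enc$n_atoms)
      role_row[[length(role_row) + 1L]] <- stats::setNames(rep(role_id, enc$n_atoms), rows)
      rxn_row[[length(rxn_row) + 1L]] <- stats::setNames(rep(i, enc$n_atoms), rows)
      real_row[[length(real_row) + 1L]] <- stats::setNames(rep(1, enc$n_atoms), rows)
      off <- off + enc$n_atoms
    }
  }
  n_rows <- off
  role_vec <- integer(n_rows); rxn_vec <- integer(n_rows); real_vec <- numeric(n_rows)
  for (x in role_row) role_vec[as.integer(names(x))] <- unname(x)
  for (x in rxn_row) rxn_vec[as.integer(names(x))] <- unname(x)
  for (x in real_row) real_vec[as.integer(names(x))] <- unname(x)

  S <- Matrix::sparseMatrix(i = unlist(feat_r), j = unlist(feat_c), x = 1,
                            dims = c(n_rows, V))
  src <- unlist(e_src); tgt <- unlist(e_tgt); code <- unlist(e_code)
  n_edges <- length(src)
  Src <- Matrix::sparseMatrix(i = seq_len(n_edges), j = src, x = 1,
                              dims = c(max(n_edges, 1L), n_rows))
  Agg <- Matrix::sparseMatrix(i = tgt, j = seq_len(n_edges), x = 1,
                              dims = c(n_rows, max(n_edges, 1L)))
  Esel <- Matrix::sparseMatrix(i = seq_len(n_edges), j = code, x = 1,
                               dims = c(max(n_edges, 1L), 4L))
  Rsel <- Matrix::sparseMatrix(i = seq_len(n_rows), j = role_vec, x = 1,
                               dims = c(n_rows, length(roles)))
  G <- Matrix::sparseMatrix(i = rxn_vec, j = seq_len(n_rows), x = 1,
                            dims = c(n_rxn, n_rows))
  attn_mask <- ifelse(outer(rxn_vec, rxn_vec, "=="), 0, -1e30)

  list(n_rows = n_rows, n_rxn = n_rxn, n_edges = n_edges,
       S = S, Src = Src, Agg = Agg, Esel = Esel, Rsel = Rsel, G = G,
       attn_mask = attn_mask,
       real_mask = matrix(real_vec, ncol = 1L), rxn_of_row = rxn_vec)
}

init_mpnn_params <- function(cfg, V) {
  d_e <- cfg$d_embed; d_h <- cfg$d_hidden
  p <- list(
    E_atom = new_param(init_mat(V, d_e) * 0.5),
    W_in = new_param(init_mat(d_e, d_h)),
    b_in = new_param(matrix(0, 1, d_h)),
    W_msg = new_param(init_mat(d_h, d_h)),
    E_bond = new_param(init_mat(4L, d_h) * 0.5)
  )
  if (cfg$update == "gru") {
    for (nm in c("z", "r", "n")) {
      p[[paste0("W", nm)]] <- new_param(init_mat(d_h, d_h))
      p[[paste0("U", nm)]] <- new_param(init_mat(d_h, d_h))
      p[[paste0("b", nm)]] <- new_param(matrix(0, 1, d_h))
    }
  } else {
    p$U_self <- new_param(init_mat(d_h, d_h))
  }
  # UNK starts at zero so unseen environments contribute nothing until
  # trained; MASK row is trainable.
  p$E_atom$value[1L, ] <- 0
  p
}

init_encoder_params <- function(cfg, n_roles) {
  d_h <- cfg$d_hidden
  d_head <- d_h %/% cfg$n_heads
  blocks <- lapply(seq_len(cfg$N), function(b) {
    list(
      Wq = lapply(seq_len(cfg$n_heads), function(h) new_param(init_mat(d_h, d_head))),
      Wk = lapply(seq_len(cfg$n_heads), function(h) new_param(init_mat(d_h, d_head))),
      Wv = lapply(seq_len(cfg$n_heads), function(h) new_param(init_mat(d_h, d_head))),
      Wo = new_param(init_mat(d_h, d_h)),
      gamma = new_param(matrix(1, 1, d_h)),
      beta = new_param(matrix(0, 1, d_h))
    )
  })
  mlp_dims <- c(d_h, cfg$d_mlp, 1L)
  mlp <- lapply(seq_len(length(mlp_dims) - 1L), function(k) {
    list(W = new_param(init_mat(mlp_dims[k], mlp_dims[k + 1L])),
         b = new_param(matrix(0, 1, mlp_dims[k + 1L])))
  })
  list(E_role = new_param(init_mat(n_roles, d_h) * 0.5), blocks = blocks,
       mlp = mlp)
}

flatten_params <- function(p) {
  out <- list()
  rec <- function(x) {
    if (is.environment(x)) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (el in x) rec(el)
  }
  rec(p)
  out
}

# MPNN stage on an assembled batch; returns the atom-state node
# (n_rows x d_hidden) with absent pseudo-rows zeroed.
mpnn_stage <- function(tape, mp, cfg, batch, training = FALSE) {
  X0 <- tp_matmul(tape, batch$S, tp_param(tape, mp$E_atom))
  H <- tp_relu(tape, tp_add(tape, tp_matmul(tape, X0, tp_param(tape, mp$W_in)),
                            tp_param(tape, mp$b_in)))
  if (cfg$L > 0 && batch$n_edges > 0) {
    for (l in seq_len(cfg$L)) {
      Hsrc <- tp_matmul(tape, batch$Src, H)
      Msg <- tp_add(tape, tp_matmul(tape, Hsrc, tp_param(tape, mp$W_msg)),
                    tp_matmul(tape, batch$Esel, tp_param(tape, mp$E_bond)))
      M <- tp_matmul(tape, batch$Agg, Msg)
      if (cfg$update == "gru") {
        z <- tp_sigmoid(tape, tp_add(tape, tp_add(tape,
          tp_matmul(tape, M, tp_param(tape, mp$Wz)),
          tp_matmul(tape, H, tp_param(tape, mp$Uz))), tp_param(tape, mp$bz)))
        r <- tp_sigmoid(tape, tp_add(tape, tp_add(tape,
          tp_matmul(tape, M, tp_param(tape, mp$Wr)),
          tp_matmul(tape, H, tp_param(tape, mp$Ur))), tp_param(tape, mp$br)))
        hn <- tp_tanh(tape, tp_add(tape, tp_add(tape,
          tp_matmul(tape, M, tp_param(tape, mp$Wn)),
          tp_matmul(tape, tp_mul(tape, r, H), tp_param(tape, mp$Un))),
          tp_param(tape, mp$bn)))
        # h' = (1 - z) * h + z * hn  ==  h + z * (hn - h)
        H <- tp_add(tape, H, tp_mul(tape, z,
               tp_add(tape, hn, tp_scale(tape, H, -1))))
      } else {
        H <- tp_add(tape, tp_matmul(tape, H, tp_param(tape, mp$U_self)), M)
      }
    }
  } else if (cfg$L > 0 && cfg$update == "gru") {
    # no edges anywhere in the batch: pure self-updates with zero messages
    for (l in seq_len(cfg$L)) {
      Z0 <- matrix(0, batch$n_rows, cfg$d_hidden)
      z <- tp_sigmoid(tape, tp_add(tape,
        tp_matmul(tape, H, tp_param(tape, mp$Uz)), tp_param(tape, mp$bz)))
      r <- tp_sigmoid(tape, tp_add(tape,
        tp_matmul(tape, H, tp_param(tape, mp$Ur)), tp_param(tape, mp$br)))
      hn <- tp_tanh(tape, tp_add(tape,
        tp_matmul(tape, tp_mul(tape, r, H), tp_param(tape, mp$Un)),
        tp_param(tape, mp$bn)))
      H <- tp_add(tape, H, tp_mul(tape, z,
             tp_add(tape, hn, tp_scale(tape, H, -1))))
    }
  } else if (cfg$L > 0) {
    for (l in seq_len(cfg$L)) {
      H <- tp_matmul(tape, H, tp_param(tape, mp$U_self))
    }
  }
  H <- tp_mul(tape, H, batch$real_mask)
  if (training && cfg$dropout > 0) {
    keep <- matrix(stats::rbinom(batch$n_rows * cfg$d_hidden, 1, 1 - cfg$dropout) /
                     (1 - cfg$dropout), batch$n_rows, cfg$d_hidden)
    H <- tp_mul(tape, H, keep)
  }
  H
}

encoder_stage <- function(tape, en, cfg, batch, H, training = FALSE) {
  X <- tp_add(tape, H, tp_matmul(tape, batch$Rsel, tp_param(tape, en$E_role)))
  d_head <- cfg$d_hidden %/% cfg$n_heads
  for (blk in en$blocks) {
    heads <- lapply(seq_len(cfg$n_heads), function(h) {
      Q <- tp_matmul(tape, X, tp_param(tape, blk$Wq[[h]]))
      K <- tp_matmul(tape, X, tp_param(tape, blk$Wk[[h]]))
      V <- tp_matmul(tape, X, tp_param(tape, blk$Wv[[h]]))
      P <- tp_softmax_rows(tape, tp_scale(tape, tp_matmul_t(tape, Q, K),
                                          1 / sqrt(d_head)),
                           mask = batch$attn_mask)
      tp_matmul(tape, P, V)
    })
    A <- tp_matmul(tape, tp_cbind(tape, heads), tp_param(tape, blk$Wo))
    if (training && cfg$dropout > 0) {
      keep <- matrix(stats::rbinom(batch$n_rows * cfg$d_hidden, 1, 1 - cfg$dropout) /
                       (1 - cfg$dropout), batch$n_rows, cfg$d_hidden)
      A <- tp_mul(tape, A, keep)
    }
    X <- tp_layernorm(tape, tp_add(tape, X, A),
                      tp_param(tape, blk$gamma), tp_param(tape, blk$beta))
  }
  X
}

head_stage <- function(tape, en, batch, X) {
  R <- tp_matmul(tape, batch$G, X)   # summation readout per reaction
  for (k in seq_along(en$mlp)) {
    R <- tp_add(tape, tp_matmul(tape, R, tp_param(tape, en$mlp[[k]]$W)),
                tp_param(tape, en$mlp[[k]]$b))
    if (k < length(en$mlp)) R <- tp_relu(tape, R)
  }
  R
}

forward_batch <- function(model, batch, training = FALSE) {
  tape <- tape_new()
  H <- mpnn_stage(tape, model$mpnn, model$cfg, batch, training)
  X <- encoder_stage(tape, model$encoder, model$cfg, batch, H, training)
  pred <- head_stage(tape, model$encoder, batch, X)
  list(tape = tape, pred = pred)
}

components_for <- function(ds, idx) {
  lapply(idx, function(i) reaction_components(ds, i))
}

#' Train an MPNN-Transformer yield model
#'
#' Minimizes mean-squared error on the (scaled) yields with Adam, early
#' stopping on a seeded validation fraction of the training reactions. All
#' components of a reaction share one message-passing network; each
#' component's atom matrix receives the additive embedding of its reaction
#' role before the encoder blocks. With a fixed seed the parameter
#' trajectory is reproducible. When a pretrained MPNN checkpoint is
#' supplied (see [pretrain_mpnn()]), only the message-passing stage (atom
#' embeddings, input projection, message/update weights) is initialized
#' from it; the encoder and head always start fresh.
#'
#' @param ds Training [reaction_dataset()].
#' @param cfg A [model_config()].
#' @param pretrained_mpnn Optional `mpnn_checkpoint`.
#' @param quiet Suppress the per-epoch progress line.
#' @return A `yield_model`.
#' @export
train_yield_model <- function(ds, cfg = model_config(),
                              pretrained_mpnn = NULL, quiet = TRUE) {
  if (n_reactions(ds) == 0) data_error("empty training set")
  with_seed(cfg$seed, {
    if (!is.null(pretrained_mpnn)) {
      stopifnot(inherits(pretrained_mpnn, "mpnn_checkpoint"))
      pc <- pretrained_mpnn$cfg
      if (pc$d_embed != cfg$d_embed || pc$d_hidden != cfg$d_hidden ||
          pc$update != cfg$update) {
        data_error("pretrained MPNN widths/update do not match the config")
      }
      vocab <- pretrained_mpnn$vocab
      mpnn <- init_mpnn_params(cfg, vocab_size(vocab))
      for (nm in names(pretrained_mpnn$mpnn_values)) {
        mpnn[[nm]]$value <- pretrained_mpnn$mpnn_values[[nm]]
      }
    } else {
      vocab <- build_env_vocab(ds$graphs)
      mpnn <- init_mpnn_params(cfg, vocab_size(vocab))
    }
    encoder <- init_encoder_params(cfg, length(ds$roles))
    model <- structure(
      list(cfg = cfg, vocab = vocab, roles = ds$roles,
           mpnn = mpnn, encoder = encoder,
           enc_cache = new.env(parent = emptyenv()),
           history = NULL),
      class = "yield_model"
    )
    y_scale <- if (cfg$yield_scale == "unit") 100 else 1
    y <- ds$table$yield / y_scale

    n <- n_reactions(ds)
    n_val <- max(0L, min(n - 1L, round(cfg$val_fraction * n)))
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)

    comps_all <- components_for(ds, seq_len(n))
    params <- flatten_params(list(model$mpnn, model$encoder))

    eval_mse <- function(idx) {
      if (length(idx) == 0) return(NA_real_)
      sq <- 0
      for (ch in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
        b <- assemble_batch(comps_all[ch], vocab, ds$roles, model$enc_cache)
        f <- forward_batch(model, b, training = FALSE)
        sq <- sq + sum((as.vector(f$pred$value) - y[ch])^2)
      }
      sq / length(idx)
    }

    # batch membership is fixed once (seeded); epochs reshuffle only the
    # batch order, so the sparse batch operators can be assembled one time
    ord0 <- sample(tr_idx)
    batch_idx <- split(ord0, ceiling(seq_along(ord0) / cfg$batch_size))
    batch_ops <- lapply(batch_idx, function(bi) {
      assemble_batch(comps_all[bi], vocab, ds$roles, model$enc_cache)
    })

    best <- list(mse = Inf, values = NULL, epoch = 0L)
    history <- list()
    step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ep_loss <- 0
      for (k in sample(seq_along(batch_idx))) {
        bi <- batch_idx[[k]]
        b <- batch_ops[[k]]
        f <- forward_batch(model, b, training = TRUE)
        diff <- tp_add(tape = f$tape, f$pred, -matrix(y[bi], ncol = 1L))
        loss <- tp_scale(f$tape, tp_sum(f$tape, tp_square(f$tape, diff)),
                         1 / length(bi))
        zero_grads(params)
        backward(f$tape, loss)
        step <- step + 1L
        adam_step(params, cfg$lr, step)
        ep_loss <- ep_loss + loss$value[1, 1] * length(bi)
      }
      train_mse <- ep_loss / length(tr_idx)
      val_mse <- eval_mse(val_idx)
      history[[epoch]] <- tibble(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse)
      if (!quiet) {
        message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_mse,
                        ifelse(is.na(val_mse), "-", sprintf("%.5f", val_mse))))
      }
      monitor <- if (is.na(val_mse)) train_mse else val_mse
      if (monitor < best$mse - 1e-9) {
        best <- list(mse = monitor, values = clone_param_values(params),
                     epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
    if (!is.null(best$values)) restore_param_values(params, best$values)
    model$history <- bind_rows(history)
    model$best_epoch <- best$epoch
    model$y_scale <- y_scale
    model
  })
}

#' Predict yields for reactions in a dataset
#'
#' @param model A `yield_model`.
#' @param ds A [reaction_dataset()] whose roles match the model's.
#' @param idx Optional reaction indices (default: all).
#' @param batch_size Forward batch size (predictions are batch-invariant).
#' @return Tibble with `reaction_id`, `predicted_yield` (percent scale).
#' @export
predict_yields <- function(model, ds, idx = NULL, batch_size = 64L) {
  stopifnot(inherits(model, "yield_model"))
  if (!all(ds$roles %in% model$roles)) {
    data_error("dataset roles (%s) not covered by model roles (%s)",
               paste(ds$roles, collapse = ","), paste(model$roles, collapse = ","))
  }
  idx <- idx %||% seq_len(n_reactions(ds))
  preds <- numeric(length(idx))
  comps <- components_for(ds, idx)
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / batch_size))
  for (ch in chunks) {
    b <- assemble_batch(comps[ch], model$vocab, model$roles, model$enc_cache)
    f <- forward_batch(model, b, training = FALSE)
    preds[ch] <- as.vector(f$pred$value)
  }
  tibble(reaction_id = ds$table$reaction_id[idx],
         predicted_yield = preds * model$y_scale)
}

#' Predict the yield of a single reaction given explicit components
#'
#' @param model A `yield_model`.
#' @param components Named list (role -> `mol_graph` or [mol_absent()]).
#' @return Predicted yield (percent scale).
#' @export
predict_yield <- function(model, components) {
  b <- assemble_batch(list(components), model$vocab, model$roles, model$enc_cache)
  f <- forward_batch(model, b, training = FALSE)
  as.vector(f$pred$value) * model$y_scale
}

#' Atom-state matrix produced by the model's message-passing stage
#'
#' Exposes the MPNN output for one molecular graph (rows in atom order),
#' mainly for inspection and testing.
#'
#' @param model A `yield_model` (or list with `cfg`, `vocab`, `mpnn`).
#' @param graph A `mol_graph`.
#' @return Numeric matrix, `n_atoms x d_hidden`.
#' @export
mpnn_forward <- function(model, graph) {
  b <- assemble_batch(list(list(x = graph)), model$vocab, "x", NULL)
  tape <- tape_new()
  H <- mpnn_stage(tape, model$mpnn, model$cfg, b, training = FALSE)
  H$value
}

#' Encoder output for one reaction
#'
#' Runs the full forward pass up to (and including) the transformer-encoder
#' blocks: per-component atom matrices from the shared MPNN, row-wise
#' concatenation, additive role embeddings, then N attention + layer-norm
#' blocks over all rows jointly. No positional encoding is used, so the
#' result is invariant to component order up to row permutation.
#'
#' @param model A `yield_model`.
#' @param components Named list (role -> `mol_graph` or [mol_absent()]).
#' @return Numeric matrix, total atoms x d_hidden.
#' @export
encode_reaction <- function(model, components) {
  b <- assemble_batch(list(components), model$vocab, model$roles, model$enc_cache)
  tape <- tape_new()
  H <- mpnn_stage(tape, model$mpnn, model$cfg, b, training = FALSE)
  X <- encoder_stage(tape, model$encoder, model$cfg, b, H, training = FALSE)
  X$value
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf(paste0("<yield_model> d_embed=%d d_hidden=%d L=%d N=%d heads=%d",
                     " | vocab %d ids | roles: %s\n"),
              x$cfg$d_embed, x$cfg$d_hidden, x$cfg$L, x$cfg$N, x$cfg$n_heads,
              length(x$vocab), paste(x$roles, collapse = ", ")))
  if (!is.null(x$best_epoch)) cat(sprintf("  best epoch: %d\n", x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a yield model
#' @param x A `yield_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_mse`, `val_mse`.
#' @export
tidy.yield_model <- function(x, ...) x$history %||% tibble()

#' One-row summary of a fitted yield model
#' @param x A `yield_model`.
#' @param ... Unused.
#' @export
glance.yield_model <- function(x, ...) {
  tibble(
    n_params = sum(vapply(flatten_params(list(x$mpnn, x$encoder)),
                          function(p) length(p$value), numeric(1))),
    vocab_size = length(x$vocab),
    best_epoch = x$best_epoch %||% NA_integer_,
    epochs_run = if (is.null(x$history)) NA_integer_ else max(x$history$epoch)
  )
}
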