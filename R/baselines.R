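# Non-neural baselines: collision-free per-role ECFP6 reaction descriptors,
# one-hot and random compound codebooks, and thin adapters over
# random-forest and gradient-boosting regressors.

#' Collision-free per-role ECFP6 descriptor space
#'
#' For each reaction role, collects every circular-substructure identifier
#' (radii 0..3, i.e. diameter 6) observed across that role's compounds,
#' orders the unique hash values decreasingly, and assigns each one its own
#' vector position. Because positions are assigned per observed hash rather
#' than by folding into a fixed width, the hash-to-position map is a
#' bijection: no two environments share a bit, and every observed feature
#' owns at least one bit. Vector lengths therefore differ across roles.
#'
#' @param ds A [reaction_dataset()] (typically the training partition; the
#'   space is frozen after building).
#' @return A `role_descriptor_space`: list with `roles`, `positions` (per
#'   role, named integer vector: hash key -> position, in decreasing hash
#'   order) and `lengths`.
#' @export
build_ecfp6_space <- function(ds) {
  if (n_reactions(ds) == 0) data_error("empty dataset")
  positions <- lapply(ds$roles, function(role) {
    hashes <- unique(unlist(lapply(ds$registry[[role]], function(s) {
      as.vector(ds$graphs[[s]]$env_ids)
    })))
    hashes <- sort(hashes, decreasing = TRUE)
    stats::setNames(seq_along(hashes), id_key(hashes))
  })
  names(positions) <- ds$roles
  structure(
    list(roles = ds$roles, positions = positions,
         lengths = vapply(positions, length, integer(1))),
    class = "role_descriptor_space"
  )
}

#' @export
print.role_descriptor_space <- function(x, ...) {
  cat("<role_descriptor_space>",
      paste(sprintf("%s=%d", x$roles, x$lengths), collapse = ", "),
      sprintf("(total %d bits)\n", sum(x$lengths)))
  invisible(x)
}

#' Per-role ECFP6 reaction descriptors
#'
#' Presence-bit vectors per component, concatenated in role-vocabulary
#' order; absent components contribute an all-zero block. Hashes unseen
#' when the space was built (inevitable under component-out splits) are
#' dropped; the drop count is attached as an attribute. The space is never
#' mutated.
#'
#' @param ds A [reaction_dataset()].
#' @param space A [build_ecfp6_space()] result covering `ds`'s roles.
#' @param idx Optional reaction indices.
#' @return Binary matrix `length(idx) x sum(space$lengths)`, attribute
#'   `dropped_hashes` = count of unseen (role, hash) occurrences.
#' @export
reaction_descriptors <- function(ds, space, idx = NULL) {
  stopifnot(inherits(space, "role_descriptor_space"))
  missing_roles <- setdiff(ds$roles, space$roles)
  if (length(missing_roles) > 0) {
    data_error("role '%s' not covered by the descriptor space", missing_roles[1])
  }
  idx <- idx %||% seq_len(n_reactions(ds))
  offsets <- c(0L, cumsum(space$lengths))
  names(offsets) <- c(space$roles, ".end")
  D <- sum(space$lengths)
  out <- matrix(0L, length(idx), D)
  dropped <- 0L
  # per-structure bit positions are cached per role
  cache <- new.env(parent = emptyenv())
  for (r in seq_along(idx)) {
    i <- idx[r]
    for (role in ds$roles) {
      s <- ds$table[[role]][i]
      if (is.na(s)) next
      key <- paste(role, s, sep = "\r")
      hit <- cache[[key]]
      if (is.null(hit)) {
        hashes <- unique(id_key(as.vector(ds$graphs[[s]]$env_ids)))
        pos <- unname(space$positions[[role]][hashes])
        hit <- list(pos = pos[!is.na(pos)] + offsets[[role]],
                    dropped = sum(is.na(pos)))
        cache[[key]] <- hit
      }
      out[r, hit$pos] <- 1L
      dropped <- dropped + hit$dropped
    }
  }
  attr(out, "dropped_hashes") <- dropped
  out
}

#' Structure-free compound codebooks (one-hot / random vectors)
#'
#' Assigns each distinct compound of each role a vector that carries no
#' structural information: a unit basis vector (`one_hot`) or a
#' seed-reproducible random vector (`random`). Reaction descriptors are the
#' per-role vectors concatenated in role order, exactly as for the ECFP6
#' case.
#'
#' @param ds A [reaction_dataset()].
#' @param mode `"one_hot"` or `"random"`.
#' @param dim Vector width per role. For `one_hot`, `NULL` auto-sizes each
#'   role to its vocabulary (an explicit `dim` smaller than a vocabulary is
#'   an error). For `random` the default is 100.
#' @param seed Seed for the random mode.
#' @return A `compound_codebook`: per-role matrix with one row per
#'   structure.
#' @export
build_codebook <- function(ds, mode = c("one_hot", "random"), dim = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  books <- with_seed(seed, {
    lapply(ds$roles, function(role) {
      st <- ds$registry[[role]]
      k <- length(st)
      if (mode == "one_hot") {
        d <- if (is.null(dim)) k else dim
        if (d < k) {
          data_error("one-hot dim %d < vocabulary size %d for role '%s'",
                     d, k, role)
        }
        m <- matrix(0, k, d)
        m[cbind(seq_len(k), seq_len(k))] <- 1
      } else {
        d <- if (is.null(dim)) 100L else dim
        m <- matrix(stats::runif(k * d), k, d)
      }
      rownames(m) <- st
      m
    })
  })
  names(books) <- ds$roles
  structure(list(roles = ds$roles, mode = mode, books = books, seed = seed),
            class = "compound_codebook")
}

#' Reaction descriptors from a compound codebook
#'
#' @param ds A [reaction_dataset()].
#' @param codebook A [build_codebook()] result.
#' @param idx Optional reaction indices.
#' @return Numeric matrix; unknown structures (absent from the codebook)
#'   and absent components give zero blocks.
#' @export
codebook_descriptors <- function(ds, codebook, idx = NULL) {
  stopifnot(inherits(codebook, "compound_codebook"))
  idx <- idx %||% seq_len(n_reactions(ds))
  widths <- vapply(codebook$books, ncol, integer(1))
  D <- sum(widths)
  ends <- cumsum(widths); starts <- c(1L, head(ends, -1L) + 1L)
  out <- matrix(0, length(idx), D)
  for (r in seq_along(idx)) {
    i <- idx[r]
    for (k in seq_along(codebook$roles)) {
      role <- codebook$roles[k]
      s <- ds$table[[role]][i]
      if (is.na(s)) next
      bk <- codebook$books[[role]]
      if (!s %in% rownames(bk)) next
      out[r, starts[k]:ends[k]] <- bk[s, ]
    }
  }
  out
}

#' Fit a forest or boosting regressor on reaction descriptors
#'
#' Thin adapter over [randomForest::randomForest()] (500 trees, the usual
#' HTE-benchmark setting) and [xgboost::xgboost()]. Boosting
#' hyper-parameters are chosen by seeded k-fold cross-validation over a
#' small documented grid with early stopping.
#'
#' @param x Descriptor matrix (finite values).
#' @param y Numeric yields.
#' @param model `"forest"` or `"boosting"`.
#' @param ntree Trees for the forest.
#' @param grid Boosting grid: data frame with `eta`, `max_depth` columns.
#' @param nrounds,nfold,early_stopping Boosting CV controls.
#' @param seed Seed for the forest / CV folds.
#' @return A `baseline_model` with a [predict][predict.baseline_model]
#'   method.
#' @export
fit_baseline <- function(x, y, model = c("forest", "boosting"),
                         ntree = 500L,
                         grid = expand.grid(eta = c(0.1, 0.3),
                                            max_depth = c(4L, 6L)),
                         nrounds = 300L, nfold = 3L, early_stopping = 10L,
                         seed = 1L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(unique(y)) < 2) {
    data_error("degenerate target: all training yields identical")
  }
  fit <- with_seed(seed, {
    if (model == "forest") {
      list(fit = randomForest::randomForest(x, y, ntree = ntree),
           meta = list(ntree = ntree))
    } else {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      best <- NULL
      for (g in seq_len(nrow(grid))) {
        cv <- xgboost::xgb.cv(
          params = list(objective = "reg:squarederror", eta = grid$eta[g],
                        max_depth = grid$max_depth[g], nthread = 1),
          data = dtrain, nrounds = nrounds, nfold = nfold,
          early_stopping_rounds = early_stopping, verbose = 0
        )
        score <- min(cv$evaluation_log$test_rmse_mean)
        best_iter <- cv$early_stop$best_iteration %||%
          which.min(cv$evaluation_log$test_rmse_mean)
        if (is.null(best) || score < best$score) {
          best <- list(score = score, eta = grid$eta[g],
                       max_depth = grid$max_depth[g], best_iter = best_iter)
        }
      }
      bst <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = best$eta,
                      max_depth = best$max_depth, nthread = 1),
        data = dtrain, nrounds = best$best_iter, verbose = 0
      )
      list(fit = bst, meta = best)
    }
  })
  structure(list(model = model, fit = fit$fit, meta = fit$meta, d = ncol(x)),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model:%s> d=%d\n", x$model, x$d))
  invisible(x)
}

#' Predict from a fitted baseline regressor
#' @param object A `baseline_model`.
#' @param newdata Descriptor matrix with the training dimensionality.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$d)
  if (object$model == "boosting") {
    as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(newdata)))
  } else {
    as.numeric(stats::predict(object$fit, newdata))
  }
}
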