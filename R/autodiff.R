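# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records nodes in creation order; backward() walks it in reverse.
# Nodes are environments: $value (matrix), $grad (accumulated), $backfn
# (closure adding into the inputs' grads). Trainable parameters live
# outside the tape as environments with $value/$grad and are wrapped per
# forward pass by tp_param(). Constant operands may be passed as plain
# (possibly sparse Matrix) matrices anywhere a node is accepted; they
# receive no gradient. This engine only implements the operations the
# message-passing network, transformer encoder and contrastive loss need.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

is_node <- function(x) is.environment(x) && !is.null(x$is_tp_node)

node_value <- function(x) if (is_node(x)) x$value else x

tp_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$is_tp_node <- TRUE
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(x, g) {
  if (is_node(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# Trainable parameter store.
new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL; p$v <- NULL   # Adam state
  p
}

tp_param <- function(tape, p) {
  nd <- tp_node(tape, p$value)
  nd$backfn <- function(g) {
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  nd
}

tp_const <- function(tape, x) tp_node(tape, x)

backward <- function(tape, loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

dense <- function(x) if (inherits(x, "Matrix")) as.matrix(x) else x

# transpose that dispatches correctly for sparse Matrix operands even when
# the Matrix package is not attached
xt <- function(x) if (inherits(x, "Matrix")) Matrix::t(x) else t(x)

# a %*% b; either side may be a constant plain/sparse matrix.
tp_matmul <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  out <- tp_node(tape, dense(av %*% bv))
  out$backfn <- function(g) {
    if (is_node(a)) acc_grad(a, dense(g %*% xt(bv)))
    if (is_node(b)) acc_grad(b, dense(xt(av) %*% g))
  }
  out
}

# a %*% t(b)
tp_matmul_t <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  out <- tp_node(tape, dense(av %*% xt(bv)))
  out$backfn <- function(g) {
    if (is_node(a)) acc_grad(a, dense(g %*% bv))
    if (is_node(b)) acc_grad(b, dense(t(g) %*% av))
  }
  out
}

# Elementwise addition; b may be a 1 x d row vector (broadcast over rows),
# an n x 1 column (broadcast over columns), or a scalar constant.
tp_add <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  bcast <- if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) "row"
           else if (is.matrix(bv) && ncol(bv) == 1L && ncol(av) > 1L) "col"
           else "none"
  val <- switch(bcast,
    row = av + matrix(bv, nrow(av), ncol(av), byrow = TRUE),
    col = av + matrix(bv, nrow(av), ncol(av)),
    none = av + bv)
  out <- tp_node(tape, val)
  out$backfn <- function(g) {
    acc_grad(a, g)
    if (is_node(b)) {
      gb <- switch(bcast,
        row = matrix(colSums(g), 1L),
        col = matrix(rowSums(g), ncol = 1L),
        none = g)
      acc_grad(b, gb)
    }
  }
  out
}

tp_scale <- function(tape, a, s) {
  out <- tp_node(tape, node_value(a) * s)
  out$backfn <- function(g) acc_grad(a, g * s)
  out
}

# Elementwise product with the same broadcasting rules as tp_add.
tp_mul <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  bcast <- if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) "row"
           else if (is.matrix(bv) && ncol(bv) == 1L && ncol(av) > 1L) "col"
           else "none"
  bfull <- switch(bcast,
    row = matrix(bv, nrow(av), ncol(av), byrow = TRUE),
    col = matrix(bv, nrow(av), ncol(av)),
    none = bv)
  out <- tp_node(tape, av * bfull)
  out$backfn <- function(g) {
    acc_grad(a, g * bfull)
    if (is_node(b)) {
      gb_full <- g * av
      gb <- switch(bcast,
        row = matrix(colSums(gb_full), 1L),
        col = matrix(rowSums(gb_full), ncol = 1L),
        none = gb_full)
      acc_grad(b, gb)
    }
  }
  out
}

tp_unary <- function(tape, a, fn, dfn) {
  av <- node_value(a)
  val <- fn(av)
  out <- tp_node(tape, val)
  out$backfn <- function(g) acc_grad(a, g * dfn(av, val))
  out
}

tp_sigmoid <- function(tape, a) {
  tp_unary(tape, a, function(x) 1 / (1 + exp(-x)), function(x, y) y * (1 - y))
}
tp_tanh <- function(tape, a) {
  tp_unary(tape, a, tanh, function(x, y) 1 - y^2)
}
tp_relu <- function(tape, a) {
  tp_unary(tape, a, function(x) pmax(x, 0), function(x, y) (x > 0) * 1)
}
tp_square <- function(tape, a) tp_unary(tape, a, function(x) x^2, function(x, y) 2 * x)

tp_sum <- function(tape, a) {
  av <- node_value(a)
  out <- tp_node(tape, matrix(sum(av), 1, 1))
  out$backfn <- function(g) acc_grad(a, matrix(g[1, 1], nrow(av), ncol(av)))
  out
}

tp_cbind <- function(tape, parts) {
  vals <- lapply(parts, node_value)
  widths <- vapply(vals, ncol, integer(1))
  out <- tp_node(tape, do.call(cbind, vals))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out$backfn <- function(g) {
    for (i in seq_along(parts)) {
      acc_grad(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  }
  out
}

# Row-wise softmax; an optional constant mask (same shape, 0 or -Inf-like
# penalties) is added to the logits first.
tp_softmax_rows <- function(tape, a, mask = NULL) {
  av <- node_value(a)
  if (!is.null(mask)) av <- av + mask
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  p <- e / rowSums(e)
  out <- tp_node(tape, p)
  out$backfn <- function(g) {
    acc_grad(a, (g - rowSums(g * p)) * p)
  }
  out
}

# Row-wise log-sum-exp with optional constant mask; returns n x 1.
tp_logsumexp_rows <- function(tape, a, mask = NULL) {
  av <- node_value(a)
  if (!is.null(mask)) av <- av + mask
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  s <- rowSums(e)
  out <- tp_node(tape, matrix(mx + log(s), ncol = 1L))
  p <- e / s
  out$backfn <- function(g) {
    acc_grad(a, matrix(g, nrow(av), ncol(av)) * p)
  }
  out
}

# Row-wise layer normalization with learnable gain/bias (1 x d params).
tp_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  av <- node_value(a)
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * inv_sd
  gv <- node_value(gamma); bv <- node_value(beta)
  val <- xhat * matrix(gv, nrow(av), d, byrow = TRUE) +
    matrix(bv, nrow(av), d, byrow = TRUE)
  out <- tp_node(tape, val)
  out$backfn <- function(g) {
    if (is_node(gamma)) acc_grad(gamma, matrix(colSums(g * xhat), 1L))
    if (is_node(beta)) acc_grad(beta, matrix(colSums(g), 1L))
    dxhat <- g * matrix(gv, nrow(av), d, byrow = TRUE)
    ga <- inv_sd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    acc_grad(a, ga)
  }
  out
}

# L2-normalize rows (for cosine similarities); composite op.
tp_l2_normalize_rows <- function(tape, a, eps = 1e-12) {
  av <- node_value(a)
  nrm <- sqrt(rowSums(av^2) + eps)
  inv <- matrix(1 / nrm, ncol = 1L)
  tp_mul(tape, a, inv_node(tape, a, inv, av, nrm, eps))
}

# Helper node: d(1/||x||)/dx handled through the chain; implemented by
# differentiating n = (sum x^2 + eps)^(-1/2) directly.
inv_node <- function(tape, a, inv, av, nrm, eps) {
  out <- tp_node(tape, inv)
  out$backfn <- function(g) {
    # g is n x 1; d inv / d a = -a / nrm^3
    acc_grad(a, matrix(g, nrow(av), ncol(av)) * (-av / nrm^3))
  }
  out
}

# Adam parameter update; params is a list of parameter environments.
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

clone_param_values <- function(params) lapply(params, function(p) p$value)

restore_param_values <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(NULL)
}

# Glorot-style initialisation.
init_mat <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}
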