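# Minimal reverse-mode automatic differentiation over dense matrices, used to
# train the graph deep learning modules. Nodes live on a tape in creation
# order; backward() walks the tape in reverse and accumulates gradients into
# parent nodes. Only the operations the encoders and losses need are provided.
# Gradient correctness is enforced by finite-difference checks in the tests.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    is_param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$is_param <- is_param
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_param <- function(tape, value) ad_node(tape, value, is_param = TRUE)
ad_const <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Seeds the scalar loss node with gradient 1 and propagates to all parameters.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  v <- a$value %*% b$value
  ad_node(tape, v, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

# S is a constant sparse matrix (dgCMatrix); only b receives gradient.
ad_spmm <- function(tape, S, b) {
  v <- as.matrix(S %*% b$value)
  ad_node(tape, v, list(b), function(g) {
    ad_accum(b, as.matrix(Matrix::crossprod(S, g)))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) ad_accum(a, g * s))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

ad_relu <- function(tape, a) {
  v <- pmax(a$value, 0)
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * (a$value > 0)))
}

ad_leakyrelu <- function(tape, a, slope = 0.2) {
  v <- pmax(a$value, 0) + slope * pmin(a$value, 0)
  ad_node(tape, v, list(a), function(g) {
    ad_accum(a, g * ifelse(a$value > 0, 1, slope))
  })
}

# PReLU with a single learnable slope (1x1 parameter node).
ad_prelu <- function(tape, a, alpha) {
  al <- alpha$value[1, 1]
  v <- pmax(a$value, 0) + al * pmin(a$value, 0)
  ad_node(tape, v, list(a, alpha), function(g) {
    ad_accum(a, g * ifelse(a$value > 0, 1, al))
    ad_accum(alpha, matrix(sum(g * pmin(a$value, 0)), 1, 1))
  })
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * v * (1 - v)))
}

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * v))
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1, 1), list(a), function(g) {
    ad_accum(a, matrix(g[1, 1], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1, 1), list(a), function(g) {
    ad_accum(a, matrix(g[1, 1] / n, nrow(a$value), ncol(a$value)))
  })
}

ad_colmeans <- function(tape, a) {
  n <- nrow(a$value)
  v <- matrix(colMeans(a$value), 1, ncol(a$value))
  ad_node(tape, v, list(a), function(g) {
    ad_accum(a, matrix(g, nrow = n, ncol = ncol(a$value), byrow = TRUE) / n)
  })
}

# Row gather: value = a[idx, ]; backward scatter-adds by index.
ad_gather_rows <- function(tape, a, idx) {
  v <- a$value[idx, , drop = FALSE]
  ad_node(tape, v, list(a), function(g) {
    agg <- rowsum(g, group = idx)
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, full)
  })
}

# Scales row i of a by s[i, 1].
ad_rowscale <- function(tape, a, s) {
  sv <- s$value[, 1]
  ad_node(tape, a$value * sv, list(a, s), function(g) {
    ad_accum(a, g * sv)
    ad_accum(s, matrix(rowSums(g * a$value), ncol = 1))
  })
}

# Sums rows of msgs into n groups: value[k, ] = sum over rows with groups==k.
ad_segsum_rows <- function(tape, msgs, groups, n_out) {
  agg <- rowsum(msgs$value, group = groups)
  v <- matrix(0, n_out, ncol(msgs$value))
  v[as.integer(rownames(agg)), ] <- agg
  ad_node(tape, v, list(msgs), function(g) {
    ad_accum(msgs, g[groups, , drop = FALSE])
  })
}

# Softmax of a column vector within segments defined by groups (shared max
# subtraction for stability). Jacobian: de = y * (g - segsum(y * g)).
ad_segment_softmax <- function(tape, e, groups) {
  ev <- e$value[, 1]
  mx <- tapply(ev, groups, max)
  shifted <- exp(ev - mx[as.character(groups)])
  den <- tapply(shifted, groups, sum)
  y <- shifted / den[as.character(groups)]
  ad_node(tape, matrix(y, ncol = 1), list(e), function(g) {
    gv <- g[, 1]
    dot <- tapply(y * gv, groups, sum)
    de <- y * (gv - dot[as.character(groups)])
    ad_accum(e, matrix(de, ncol = 1))
  })
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  v <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, v, nodes, function(g) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# value = z %*% t(z); backward dz = (G + t(G)) %*% z.
ad_tcrossprod <- function(tape, z) {
  v <- tcrossprod(z$value)
  ad_node(tape, v, list(z), function(g) {
    ad_accum(z, (g + t(g)) %*% z$value)
  })
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# Mean binary cross-entropy from logits with optional positive-class weight:
#   l = pos_weight * t * softplus(-x) + (1 - t) * softplus(x), averaged.
ad_bce_logits <- function(tape, logits, target, pos_weight = 1) {
  x <- logits$value
  l <- pos_weight * target * softplus(-x) + (1 - target) * softplus(x)
  n <- length(x)
  ad_node(tape, matrix(mean(l), 1, 1), list(logits), function(g) {
    s <- 1 / (1 + exp(-x))
    dx <- pos_weight * target * (s - 1) + (1 - target) * s
    ad_accum(logits, g[1, 1] * dx / n)
  })
}

# --- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p))),
    v = lapply(params, function(p) array(0, dim(p))),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
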