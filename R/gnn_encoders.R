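# Registry of graph neural network encoder families, each implemented from
# its message-passing formula. The exported *_forward functions are plain
# matrix implementations of a single convolution (the reference surface that
# the per-node oracles in the tests check); training builds the same
# computations on the autodiff tape via ad_encoder_forward so the two paths
# can be cross-validated at fixed parameters.

#' Available encoder families
#'
#' @return Character vector of registered family names.
#' @export
encoder_families <- function() {
  c("gcn", "sgc", "tag", "chebyshev", "sage", "gatv2")
}

#' Describe an encoder
#'
#' @param family One of [encoder_families()].
#' @param in_dim,hidden_dim,out_dim Layer widths (positive integers).
#' @param hops_K Propagation hops for sgc/tag/chebyshev (default 2).
#' @param heads Attention heads for gatv2 (default 1); hidden heads are
#'   concatenated, the output layer uses a single head.
#' @param activation `"prelu"` (the deep-graph-infomax convention) or
#'   `"relu"` (used inside the variational graph autoencoder).
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(family, in_dim, hidden_dim = 64, out_dim = 32,
                         hops_K = 2, heads = 1,
                         activation = c("prelu", "relu")) {
  activation <- match.arg(activation)
  if (!family %in% encoder_families()) {
    stop(sprintf(
      "unknown encoder family '%s'; available families: %s",
      family, paste(encoder_families(), collapse = ", ")
    ), call. = FALSE)
  }
  stopifnot(in_dim >= 1, hidden_dim >= 1, out_dim >= 1, hops_K >= 1, heads >= 1)
  structure(
    list(
      family = family, in_dim = as.integer(in_dim),
      hidden_dim = as.integer(hidden_dim), out_dim = as.integer(out_dim),
      hops_K = as.integer(hops_K), heads = as.integer(heads),
      activation = activation
    ),
    class = "encoder_spec"
  )
}

glorot <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -lim, lim), din, dout)
}

# Parameters of one convolution layer taking din columns to dout.
init_layer_params <- function(family, din, dout, spec, heads = 1L) {
  p <- list()
  if (family %in% c("gcn", "sgc")) {
    p$W <- glorot(din, dout)
  } else if (family %in% c("tag", "chebyshev")) {
    for (k in 0:spec$hops_K) p[[paste0("W", k)]] <- glorot(din, dout)
  } else if (family == "sage") {
    p$Ws <- glorot(din, dout)
    p$Wn <- glorot(din, dout)
  } else if (family == "gatv2") {
    for (h in seq_len(heads)) {
      p[[paste0("Wl", h)]] <- glorot(din, dout)
      p[[paste0("Wr", h)]] <- glorot(din, dout)
      p[[paste0("a", h)]] <- glorot(dout, 1)
    }
  }
  p
}

# Layer widths for a stacked encoder ending at out_dim. SGC is a single
# linear propagation by definition; all other families use one hidden layer.
encoder_dims <- function(spec, n_layers = 2L) {
  if (n_layers == 1L) {
    return(c(spec$in_dim, spec$out_dim))
  }
  if (spec$family == "sgc") {
    return(c(spec$in_dim, spec$out_dim))
  }
  c(spec$in_dim, spec$hidden_dim, spec$out_dim)
}

#' Instantiate an encoder with seeded Glorot-uniform parameters
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   parameters.
#' @param n_layers Number of stacked convolutions (default 2: one hidden
#'   layer, linear output). `1` builds the single-convolution form used as
#'   the first layer of the variational graph autoencoder.
#' @return An `encoder` object with `spec` and a flat named parameter list.
#' @export
make_encoder <- function(spec, seed = 0, n_layers = 2L) {
  stopifnot(inherits(spec, "encoder_spec"))
  set.seed(as.integer(seed))
  dims <- encoder_dims(spec, n_layers)
  params <- list()
  nl <- length(dims) - 1L
  for (l in seq_len(nl)) {
    final <- l == nl && n_layers > 1L
    heads <- if (spec$family == "gatv2" && !final) spec$heads else 1L
    din <- dims[l] * (if (spec$family == "gatv2" && l > 1L) spec$heads else 1L)
    lp <- init_layer_params(spec$family, din, dims[l + 1L], spec, heads)
    names(lp) <- paste0("L", l, ".", names(lp))
    params <- c(params, lp)
    if (!final && spec$activation == "prelu") {
      params[[paste0("L", l, ".alpha")]] <- matrix(0.25, 1, 1)
    }
  }
  structure(list(spec = spec, params = params, n_layers = as.integer(nl)),
    class = "encoder"
  )
}

# ---- plain single-convolution reference implementations ------------------

as_dense <- function(x) as.matrix(x)

#' Graph convolution forward pass
#'
#' Stacked layers `H <- act(A_norm %*% H %*% W)`; the final layer is linear.
#'
#' @param X Feature matrix (n x p).
#' @param A_norm Symmetrically normalized adjacency.
#' @param W_layers A single weight matrix or a list of per-layer weights.
#' @param activation Nonlinearity between layers (default ReLU).
#' @return n x out matrix.
#' @export
gcn_forward <- function(X, A_norm, W_layers, activation = function(h) pmax(h, 0)) {
  if (!is.list(W_layers)) W_layers <- list(W_layers)
  H <- as_dense(X)
  for (l in seq_along(W_layers)) {
    H <- as_dense(A_norm %*% H) %*% W_layers[[l]]
    if (l < length(W_layers)) H <- activation(H)
  }
  H
}

#' Simplified graph convolution forward pass
#'
#' `A_norm^K %*% X %*% W` with no intermediate nonlinearity.
#'
#' @inheritParams gcn_forward
#' @param W Weight matrix.
#' @param K Number of propagation hops (default 2).
#' @return n x out matrix.
#' @export
sgc_forward <- function(X, A_norm, W, K = 2) {
  stopifnot(K >= 1)
  H <- as_dense(X)
  for (k in seq_len(K)) H <- as_dense(A_norm %*% H)
  H %*% W
}

#' Topology-adaptive graph convolution forward pass
#'
#' `sum_{k=0..K} A_norm^k %*% X %*% W_k`.
#'
#' @inheritParams gcn_forward
#' @param W_list List of `K + 1` weight matrices, hop 0 first.
#' @return n x out matrix.
#' @export
tag_forward <- function(X, A_norm, W_list) {
  P <- as_dense(X)
  out <- P %*% W_list[[1]]
  for (k in seq_along(W_list)[-1]) {
    P <- as_dense(A_norm %*% P)
    out <- out + P %*% W_list[[k]]
  }
  out
}

#' Chebyshev spectral convolution forward pass
#'
#' Chebyshev basis on the scaled Laplacian `Lhat = 2L/lambda_max - I` with
#' `L = I - A_norm` and `lambda_max` fixed at 2 (the normalized-Laplacian
#' upper bound), so `Lhat = -A_norm`. Basis: `T_0 = X`, `T_1 = Lhat X`,
#' `T_k = 2 Lhat T_{k-1} - T_{k-2}`; output `sum_k T_k W_k`.
#'
#' @inheritParams tag_forward
#' @return n x out matrix.
#' @export
cheb_forward <- function(X, A_norm, W_list) {
  lhat <- function(H) -as_dense(A_norm %*% H)
  Tprev <- as_dense(X)
  out <- Tprev %*% W_list[[1]]
  if (length(W_list) > 1) {
    Tcur <- lhat(Tprev)
    out <- out + Tcur %*% W_list[[2]]
    for (k in seq_along(W_list)[-(1:2)]) {
      Tnext <- 2 * lhat(Tcur) - Tprev
      out <- out + Tnext %*% W_list[[k]]
      Tprev <- Tcur
      Tcur <- Tnext
    }
  }
  out
}

#' GraphSAGE (mean aggregator) forward pass
#'
#' `h_i = act(W_self x_i + W_neigh mean_{j in N(i)} x_j)`; isolated spots use
#' a zero neighbor mean. `A` is the structural (zero-diagonal) adjacency.
#'
#' @inheritParams gcn_forward
#' @param A Binary symmetric adjacency, zero diagonal.
#' @param W_self,W_neigh Weight matrices.
#' @return n x out matrix.
#' @export
sage_forward <- function(X, A, W_self, W_neigh,
                         activation = function(h) pmax(h, 0)) {
  X <- as_dense(X)
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / d, 0)
  M <- Matrix::Diagonal(x = dinv) %*% A
  activation(X %*% W_self + as_dense(M %*% X) %*% W_neigh)
}

#' GATv2 attention convolution forward pass
#'
#' Per directed edge `j -> i` over `N(i) union {i}`:
#' `e_ij = a' LeakyReLU(W_l x_j + W_r x_i)`, attention
#' `alpha_ij = softmax_j(e_ij)`, and `h_i = sum_j alpha_ij W_l x_j`.
#' Multiple heads are concatenated.
#'
#' @inheritParams sage_forward
#' @param W_l,W_r Source/target weight matrices (or lists, one per head).
#' @param a Attention vectors (dout x 1 matrix, or list per head).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @param return_attention Also return the per-edge attention list.
#' @return n x (out * heads) matrix (or a list when `return_attention`).
#' @export
gatv2_forward <- function(X, A, W_l, W_r, a, leaky_slope = 0.2,
                          return_attention = FALSE) {
  if (!is.list(W_l)) {
    W_l <- list(W_l)
    W_r <- list(W_r)
    a <- list(a)
  }
  X <- as_dense(X)
  n <- nrow(X)
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  Matrix::diag(A) <- 0
  trip <- Matrix::summary(Matrix::drop0(A))
  src <- c(trip$j, seq_len(n))
  dst <- c(trip$i, seq_len(n))
  heads_out <- list()
  att <- list()
  for (h in seq_along(W_l)) {
    XL <- X %*% W_l[[h]]
    XR <- X %*% W_r[[h]]
    z <- XL[src, , drop = FALSE] + XR[dst, , drop = FALSE]
    z <- pmax(z, 0) + leaky_slope * pmin(z, 0)
    e <- as.vector(z %*% a[[h]])
    mx <- tapply(e, dst, max)
    ex <- exp(e - as.numeric(mx[as.character(dst)]))
    den <- tapply(ex, dst, sum)
    alpha <- as.numeric(ex / den[as.character(dst)])
    msg <- XL[src, , drop = FALSE] * alpha
    out <- matrix(0, n, ncol(XL))
    agg <- rowsum(msg, dst)
    out[as.integer(rownames(agg)), ] <- agg
    heads_out[[h]] <- out
    att[[h]] <- data.frame(src = src, dst = dst, alpha = alpha)
  }
  H <- do.call(cbind, heads_out)
  if (return_attention) list(H = H, attention = att) else H
}

# ---- autodiff forwards ---------------------------------------------------

# Per-graph constants shared by every layer of a forward pass.
graph_consts <- function(g) {
  list(
    An = methods::as(g$A_norm, "CsparseMatrix"),
    M = graph_rownorm(g),
    edges = graph_edges_with_self(g),
    n = nrow(g$A)
  )
}

ad_layer_forward <- function(tape, family, X, gc, pn, prefix, spec, heads) {
  p <- function(nm) pn[[paste0(prefix, ".", nm)]]
  if (family == "gcn") {
    return(ad_matmul(tape, ad_spmm(tape, gc$An, X), p("W")))
  }
  if (family == "sgc") {
    H <- X
    for (k in seq_len(spec$hops_K)) H <- ad_spmm(tape, gc$An, H)
    return(ad_matmul(tape, H, p("W")))
  }
  if (family == "tag") {
    P <- X
    out <- ad_matmul(tape, P, p("W0"))
    for (k in seq_len(spec$hops_K)) {
      P <- ad_spmm(tape, gc$An, P)
      out <- ad_add(tape, out, ad_matmul(tape, P, p(paste0("W", k))))
    }
    return(out)
  }
  if (family == "chebyshev") {
    Tprev <- X
    out <- ad_matmul(tape, Tprev, p("W0"))
    if (spec$hops_K >= 1) {
      Tcur <- ad_scale(tape, ad_spmm(tape, gc$An, Tprev), -1)
      out <- ad_add(tape, out, ad_matmul(tape, Tcur, p("W1")))
      if (spec$hops_K >= 2) {
        for (k in 2:spec$hops_K) {
          Tnext <- ad_add(
            tape,
            ad_scale(tape, ad_spmm(tape, gc$An, Tcur), -2),
            ad_scale(tape, Tprev, -1)
          )
          out <- ad_add(tape, out, ad_matmul(tape, Tnext, p(paste0("W", k))))
          Tprev <- Tcur
          Tcur <- Tnext
        }
      }
    }
    return(out)
  }
  if (family == "sage") {
    return(ad_add(
      tape,
      ad_matmul(tape, X, p("Ws")),
      ad_matmul(tape, ad_spmm(tape, gc$M, X), p("Wn"))
    ))
  }
  if (family == "gatv2") {
    hs <- vector("list", heads)
    for (h in seq_len(heads)) {
      XL <- ad_matmul(tape, X, p(paste0("Wl", h)))
      XR <- ad_matmul(tape, X, p(paste0("Wr", h)))
      z <- ad_add(
        tape,
        ad_gather_rows(tape, XL, gc$edges$src),
        ad_gather_rows(tape, XR, gc$edges$dst)
      )
      e <- ad_matmul(tape, ad_leakyrelu(tape, z, 0.2), p(paste0("a", h)))
      alpha <- ad_segment_softmax(tape, e, gc$edges$dst)
      msg <- ad_rowscale(tape, ad_gather_rows(tape, XL, gc$edges$src), alpha)
      hs[[h]] <- ad_segsum_rows(tape, msg, gc$edges$dst, gc$n)
    }
    return(if (heads == 1L) hs[[1]] else ad_cbind(tape, hs))
  }
  stop(sprintf("unknown encoder family '%s'", family), call. = FALSE)
}

# Full stacked forward on the tape. `final_linear = TRUE` leaves the last
# layer without activation (the embedding convention); FALSE applies the
# activation to every layer (the single-layer autoencoder front end).
ad_encoder_forward <- function(tape, enc, pn, X, gc, final_linear = TRUE) {
  spec <- enc$spec
  H <- X
  for (l in seq_len(enc$n_layers)) {
    final <- l == enc$n_layers
    heads <- if (spec$family == "gatv2" && !(final && final_linear)) spec$heads else 1L
    heads <- if (spec$family == "gatv2" && final && enc$n_layers > 1L) 1L else heads
    H <- ad_layer_forward(
      tape, spec$family, H, gc, pn, paste0("L", l), spec, heads
    )
    if (!final || !final_linear) {
      H <- if (spec$activation == "prelu" &&
        !is.null(pn[[paste0("L", l, ".alpha")]])) {
        ad_prelu(tape, H, pn[[paste0("L", l, ".alpha")]])
      } else {
        ad_relu(tape, H)
      }
    }
  }
  H
}

#' Run an encoder forward at its current parameters
#'
#' Deterministic inference pass (no sampling, no gradient); used to extract
#' embeddings after training and to cross-check the training-path forward
#' against the exported single-convolution implementations.
#'
#' @param enc An `encoder` from [make_encoder()].
#' @param X Feature matrix.
#' @param g A `spatial_graph`.
#' @param final_linear Leave the last layer linear (default TRUE).
#' @return n x out matrix.
#' @export
encoder_embed <- function(enc, X, g, final_linear = TRUE) {
  tape <- ad_tape()
  pn <- lapply(enc$params, function(p) ad_const(tape, p))
  Xn <- ad_const(tape, as.matrix(X))
  gc <- graph_consts(g)
  ad_encoder_forward(tape, enc, pn, Xn, gc, final_linear = final_linear)$value
}
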