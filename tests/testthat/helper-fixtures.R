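# Shared fixtures and independent oracles. Everything here is deliberately
# naive (per-node loops, explicit pair counting) so it cannot share a bug
# with the vectorized implementations under test.

make_rand_graph <- function(n, k = 3, seed = 1, self_loops = TRUE) {
  set.seed(seed)
  coords <- matrix(stats::runif(2 * n), n, 2)
  list(g = build_graph(coords, mode = "knn", k = k, self_loops = self_loops),
       coords = coords)
}

rand_X <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p)
}

# Permute a spatial_graph without rebuilding from coordinates (avoids
# distance tie-break differences).
permute_graph <- function(g, perm) {
  A2 <- g$A[perm, perm]
  structure(
    list(A = A2, A_norm = normalize_adjacency(A2),
         degree = as.integer(Matrix::rowSums(A2)), params = g$params),
    class = "spatial_graph"
  )
}

# --- per-node message-passing oracles -------------------------------------

oracle_gcn_layer <- function(X, An, W) {
  An <- as.matrix(An)
  n <- nrow(X)
  agg <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) agg[i, ] <- agg[i, ] + An[i, j] * X[j, ]
  }
  agg %*% W
}

oracle_sgc <- function(X, An, W, K) {
  H <- X
  for (k in seq_len(K)) H <- oracle_gcn_layer(H, An, diag(ncol(H)))
  H %*% W
}

oracle_tag <- function(X, An, W_list) {
  P <- X
  out <- P %*% W_list[[1]]
  for (k in seq_along(W_list)[-1]) {
    P <- oracle_gcn_layer(P, An, diag(ncol(P)))
    out <- out + P %*% W_list[[k]]
  }
  out
}

# Chebyshev via explicit polynomial coefficients in dense Lhat = -An:
# T0 = I, T1 = L, T2 = 2L^2 - I, T3 = 4L^3 - 3L.
oracle_cheb <- function(X, An, W_list) {
  L <- -as.matrix(An)
  n <- nrow(L)
  powers <- list(diag(n), L, 2 * L %*% L - diag(n),
                 4 * L %*% L %*% L - 3 * L)
  out <- matrix(0, nrow(X), ncol(W_list[[1]]))
  for (k in seq_along(W_list)) {
    out <- out + (powers[[k]] %*% X) %*% W_list[[k]]
  }
  out
}

oracle_sage <- function(X, A, W_self, W_neigh, act = function(h) pmax(h, 0)) {
  A <- as.matrix(A)
  diag(A) <- 0
  n <- nrow(X)
  out <- matrix(0, n, ncol(W_self))
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    mean_nb <- if (length(nb) == 0) {
      rep(0, ncol(X))
    } else {
      colMeans(X[nb, , drop = FALSE])
    }
    out[i, ] <- act(X[i, ] %*% W_self + mean_nb %*% W_neigh)
  }
  out
}

oracle_gatv2 <- function(X, A, W_l, W_r, a, slope = 0.2) {
  A <- as.matrix(A)
  diag(A) <- 0
  n <- nrow(X)
  out <- matrix(0, n, ncol(W_l))
  for (i in seq_len(n)) {
    nb <- c(which(A[i, ] > 0), i)
    e <- vapply(nb, function(j) {
      z <- as.vector(X[j, ] %*% W_l + X[i, ] %*% W_r)
      z <- pmax(z, 0) + slope * pmin(z, 0)
      sum(z * as.vector(a))
    }, numeric(1))
    al <- exp(e - max(e))
    al <- al / sum(al)
    for (t in seq_along(nb)) {
      out[i, ] <- out[i, ] + al[t] * (X[nb[t], ] %*% W_l)
    }
  }
  out
}

# --- partition / metric oracles -------------------------------------------

# All set partitions of n elements as restricted growth strings.
partitions_of <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(integer(0), 0L)
  out
}

oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  np <- s11 + s10 + s01 + s00
  expected <- (s11 + s10) * (s11 + s01) / np
  mx <- 0.5 * ((s11 + s10) + (s11 + s01))
  if (mx == expected) return(ifelse(s11 == expected, 1, 0))
  (s11 - expected) / (mx - expected)
}

oracle_nmi_entropy <- function(a, b) {
  n <- length(a)
  ent <- function(l) {
    p <- table(l) / n
    -sum(p * log(p))
  }
  mi <- 0
  for (u in unique(a)) {
    for (v in unique(b)) {
      pij <- sum(a == u & b == v) / n
      if (pij > 0) mi <- mi + pij * log(pij / ((sum(a == u) / n) * (sum(b == v) / n)))
    }
  }
  denom <- (ent(a) + ent(b)) / 2
  if (denom == 0) return(1)
  mi / denom
}

# Rank-based AUC of scores for positives vs negatives.
auc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# The layered 5-domain study preset used by the training-level checks.
layered_preset <- function(seed) {
  synthetic_config(
    n_spots = 800, n_genes = 200, n_domains = 5, geometry = "layers",
    signal_strength = 3, program_size = 40, noise_sd = 1,
    dropout_rate = 0, seed = seed
  )
}

prelu_act <- function(alpha) function(h) pmax(h, 0) + alpha * pmin(h, 0)
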