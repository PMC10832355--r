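# Encoder registry: the exported matrix forwards against per-node oracles,
# the training-path (tape) forward against the exported forwards, and
# structural properties (permutation equivariance, attention normalization).

ns <- asNamespace("spadom")
graph_consts <- get("graph_consts", ns)
graph_offdiag <- get("graph_offdiag", ns)

test_that("encoder registry exposes the six families and rejects unknown ones", {
  expect_setequal(
    encoder_families(),
    c("gcn", "sgc", "tag", "chebyshev", "sage", "gatv2")
  )
  expect_error(
    encoder_spec("transformer", in_dim = 4),
    "unknown encoder family 'transformer'.*gcn"
  )
})

test_that("seeded encoder construction is reproducible and seed-sensitive", {
  spec <- encoder_spec("gcn", in_dim = 5, hidden_dim = 4, out_dim = 3)
  e1 <- make_encoder(spec, seed = 7)
  e2 <- make_encoder(spec, seed = 7)
  e3 <- make_encoder(spec, seed = 8)
  expect_identical(e1$params, e2$params)
  expect_false(isTRUE(all.equal(e1$params$L1.W, e3$params$L1.W)))
})

test_that("single-hop convolution on a two-spot clique has the closed-form half-sum output", {
  A <- Matrix::Matrix(1, 2, 2, sparse = TRUE) # clique with self loops
  An <- normalize_adjacency(A)
  expect_equal(as.matrix(An), matrix(0.5, 2, 2),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  X <- diag(2)
  out <- sgc_forward(X, An, diag(2), K = 2)
  expect_equal(as.matrix(out), matrix(0.5, 2, 2))
  out1 <- gcn_forward(X, An, diag(2))
  expect_equal(as.matrix(out1), matrix(0.5, 2, 2))
})

test_that("each exported convolution matches its per-node aggregation oracle", {
  fx <- make_rand_graph(14, k = 3, seed = 3)
  An <- fx$g$A_norm
  A_off <- graph_offdiag(fx$g)
  X <- rand_X(14, 4, seed = 4)
  set.seed(5)
  W <- matrix(stats::rnorm(4 * 3), 4, 3)
  W_list <- replicate(3, matrix(stats::rnorm(4 * 3), 4, 3), simplify = FALSE)
  Ws <- matrix(stats::rnorm(4 * 3), 4, 3)
  Wn <- matrix(stats::rnorm(4 * 3), 4, 3)
  a <- matrix(stats::rnorm(3), 3, 1)

  expect_equal(gcn_forward(X, An, W), oracle_gcn_layer(X, An, W),
    tolerance = 1e-10
  )
  expect_equal(sgc_forward(X, An, W, K = 2), oracle_sgc(X, An, W, K = 2),
    tolerance = 1e-10
  )
  expect_equal(tag_forward(X, An, W_list), oracle_tag(X, An, W_list),
    tolerance = 1e-10
  )
  expect_equal(cheb_forward(X, An, W_list), oracle_cheb(X, An, W_list),
    tolerance = 1e-10
  )
  expect_equal(sage_forward(X, A_off, Ws, Wn), oracle_sage(X, A_off, Ws, Wn),
    tolerance = 1e-10
  )
  expect_equal(gatv2_forward(X, A_off, Ws, Wn, a),
    oracle_gatv2(X, A_off, Ws, Wn, a),
    tolerance = 1e-10
  )
})

# Compose the exported matrix forwards into the stacked embedding at the
# encoder's stored parameters; hidden layers use PReLU (slope 0.25 at init),
# the final layer is linear.
compose_exported <- function(enc, X, g) {
  spec <- enc$spec
  p <- enc$params
  An <- g$A_norm
  A_off <- graph_offdiag(g)
  act <- prelu_act(0.25)
  if (spec$family == "gcn") {
    H <- act(gcn_forward(X, An, p$L1.W))
    return(gcn_forward(H, An, p$L2.W))
  }
  if (spec$family == "sgc") {
    return(sgc_forward(X, An, p$L1.W, K = spec$hops_K))
  }
  if (spec$family == "tag") {
    wl <- function(l) lapply(0:spec$hops_K, function(k) p[[paste0("L", l, ".W", k)]])
    return(tag_forward(act(tag_forward(X, An, wl(1))), An, wl(2)))
  }
  if (spec$family == "chebyshev") {
    wl <- function(l) lapply(0:spec$hops_K, function(k) p[[paste0("L", l, ".W", k)]])
    return(cheb_forward(act(cheb_forward(X, An, wl(1))), An, wl(2)))
  }
  if (spec$family == "sage") {
    H <- sage_forward(X, A_off, p$L1.Ws, p$L1.Wn, activation = act)
    return(sage_forward(H, A_off, p$L2.Ws, p$L2.Wn, activation = identity))
  }
  if (spec$family == "gatv2") {
    hs <- seq_len(spec$heads)
    H <- act(gatv2_forward(
      X, A_off,
      lapply(hs, function(h) p[[paste0("L1.Wl", h)]]),
      lapply(hs, function(h) p[[paste0("L1.Wr", h)]]),
      lapply(hs, function(h) p[[paste0("L1.a", h)]])
    ))
    return(gatv2_forward(H, A_off, p$L2.Wl1, p$L2.Wr1, p$L2.a1))
  }
  stop("unreached")
}

test_that("the training-path forward agrees with the composed exported forwards for every family", {
  fx <- make_rand_graph(16, k = 3, seed = 9)
  X <- rand_X(16, 5, seed = 10)
  for (family in encoder_families()) {
    spec <- encoder_spec(family,
      in_dim = 5, hidden_dim = 4, out_dim = 3,
      hops_K = 2, heads = 2
    )
    enc <- make_encoder(spec, seed = 11)
    E_tape <- encoder_embed(enc, X, fx$g)
    E_ref <- compose_exported(enc, X, fx$g)
    expect_equal(E_tape, E_ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("embeddings are equivariant to spot reordering for every family", {
  fx <- make_rand_graph(18, k = 3, seed = 13)
  X <- rand_X(18, 4, seed = 14)
  set.seed(15)
  perm <- sample.int(18)
  g2 <- permute_graph(fx$g, perm)
  for (family in encoder_families()) {
    spec <- encoder_spec(family,
      in_dim = 4, hidden_dim = 4, out_dim = 3,
      hops_K = 2, heads = 2
    )
    enc <- make_encoder(spec, seed = 16)
    E <- encoder_embed(enc, X, fx$g)
    E2 <- encoder_embed(enc, X[perm, , drop = FALSE], g2)
    expect_equal(E2, E[perm, , drop = FALSE], tolerance = 1e-9)
  }
})

test_that("attention coefficients are a probability distribution over each spot's in-neighborhood", {
  fx <- make_rand_graph(12, k = 3, seed = 17)
  A_off <- graph_offdiag(fx$g)
  X <- rand_X(12, 4, seed = 18)
  set.seed(19)
  res <- gatv2_forward(
    X, A_off, matrix(stats::rnorm(12), 4, 3),
    matrix(stats::rnorm(12), 4, 3), matrix(stats::rnorm(3), 3, 1),
    return_attention = TRUE
  )
  att <- res$attention[[1]]
  sums <- tapply(att$alpha, att$dst, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 12), tolerance = 1e-12)
  expect_true(all(att$alpha > 0))
})

test_that("simplified graph convolution collapses to one linear propagation regardless of depth request", {
  spec <- encoder_spec("sgc", in_dim = 4, hidden_dim = 10, out_dim = 3)
  enc <- make_encoder(spec, seed = 1)
  expect_identical(enc$n_layers, 1L)
  expect_named(enc$params, "L1.W")
  expect_identical(dim(enc$params$L1.W), c(4L, 3L))
})

test_that("multi-head attention widens the hidden layer and the output layer stays single-headed", {
  spec <- encoder_spec("gatv2", in_dim = 4, hidden_dim = 3, out_dim = 2, heads = 2)
  enc <- make_encoder(spec, seed = 1)
  expect_true(all(c("L1.Wl1", "L1.Wl2", "L2.Wl1") %in% names(enc$params)))
  expect_false("L2.Wl2" %in% names(enc$params))
  # second layer consumes the concatenated heads
  expect_identical(dim(enc$params$L2.Wl1), c(6L, 2L))
  fx <- make_rand_graph(10, k = 3, seed = 2)
  E <- encoder_embed(enc, rand_X(10, 4), fx$g)
  expect_identical(dim(E), c(10L, 2L))
})
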