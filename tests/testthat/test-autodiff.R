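# Gradient correctness of the tape-based reverse-mode engine, checked by
# central finite differences through the exact computations the two training
# loops build.

ns <- asNamespace("spadom")
for (nm in c(
  "ad_tape", "ad_param", "ad_const", "ad_backward", "ad_matmul", "ad_spmm",
  "ad_add", "ad_scale", "ad_mul", "ad_transpose", "ad_relu", "ad_prelu",
  "ad_sigmoid", "ad_exp", "ad_sum", "ad_colmeans", "ad_tcrossprod",
  "ad_segment_softmax", "ad_bce_logits", "ad_encoder_forward",
  "graph_consts", "adam_init", "adam_step", "glorot"
)) {
  assign(nm, get(nm, ns))
}

# Largest relative disagreement between tape gradients and central
# finite differences, over every entry of every parameter.
grad_check <- function(loss_fn, params, eps = 1e-5) {
  res <- loss_fn(params)
  ad_backward(res$tape, res$loss)
  an <- lapply(res$pn, function(nd) nd$grad)
  worst <- 0
  for (nm in names(params)) {
    P <- params[[nm]]
    for (i in seq_along(P)) {
      pp <- params
      pp[[nm]][i] <- P[i] + eps
      pm <- params
      pm[[nm]][i] <- P[i] - eps
      num <- (loss_fn(pp)$loss$value[1, 1] -
        loss_fn(pm)$loss$value[1, 1]) / (2 * eps)
      a <- if (is.null(an[[nm]])) 0 else an[[nm]][i]
      worst <- max(worst, abs(a - num) / max(1, abs(num)))
    }
  }
  worst
}

make_infomax_loss <- function(spec, n_layers, X, gc) {
  function(params) {
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_param(tape, p))
    H <- ad_encoder_forward(
      tape, list(spec = spec, n_layers = n_layers), pn,
      ad_const(tape, X), gc
    )
    S <- ad_sigmoid(tape, ad_colmeans(tape, H))
    WdS <- ad_matmul(tape, pn$Wd, ad_transpose(tape, S))
    scores <- ad_matmul(tape, H, WdS)
    loss <- ad_bce_logits(tape, scores, 1)
    list(tape = tape, loss = loss, pn = pn)
  }
}

test_that("encoder-through-discriminator gradients match finite differences for every family", {
  fx <- make_rand_graph(10, k = 3, seed = 7)
  gc <- graph_consts(fx$g)
  X <- rand_X(10, 3, seed = 8)
  for (family in encoder_families()) {
    spec <- encoder_spec(family,
      in_dim = 3, hidden_dim = 3, out_dim = 2,
      hops_K = 2, heads = 2, activation = "prelu"
    )
    enc <- make_encoder(spec, seed = 11)
    set.seed(12)
    params <- c(enc$params, list(Wd = glorot(2, 2)))
    worst <- grad_check(make_infomax_loss(spec, enc$n_layers, X, gc), params)
    expect_lt(worst, 1e-6)
  }
})

make_vgae_loss <- function(spec1, X, gc, A_target, epsilon, pos_weight,
                           kl_scale, share) {
  n <- nrow(X)
  function(params) {
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_param(tape, p))
    Xt <- ad_encoder_forward(
      tape, list(spec = spec1, n_layers = 1L), pn,
      ad_const(tape, X), gc,
      final_linear = FALSE
    )
    AXt <- ad_spmm(tape, gc$An, Xt)
    mu <- ad_matmul(tape, AXt, pn$W1)
    ls <- if (share) mu else ad_matmul(tape, AXt, pn$W1_sigma)
    sig <- ad_exp(tape, ad_scale(tape, ls, 0.5))
    Z <- ad_add(tape, mu, ad_mul(tape, sig, ad_const(tape, epsilon)))
    logits <- ad_tcrossprod(tape, Z)
    recon <- ad_bce_logits(tape, logits, A_target, pos_weight = pos_weight)
    kl_terms <- ad_add(
      tape,
      ad_add(tape, ad_exp(tape, ls), ad_mul(tape, mu, mu)),
      ad_scale(tape, ls, -1)
    )
    kl <- ad_scale(tape, ad_sum(tape, kl_terms), 0.5 / n)
    loss <- ad_add(tape, recon, ad_scale(tape, kl, kl_scale))
    list(tape = tape, loss = loss, pn = pn)
  }
}

test_that("variational autoencoder gradients match finite differences with shared and separate heads", {
  fx <- make_rand_graph(9, k = 3, seed = 21)
  gc <- graph_consts(fx$g)
  X <- rand_X(9, 3, seed = 22)
  A_target <- as.matrix(fx$g$A)
  diag(A_target) <- 1
  set.seed(23)
  epsilon <- matrix(stats::rnorm(9 * 2), 9, 2)
  spec1 <- encoder_spec("gcn",
    in_dim = 3, hidden_dim = 3, out_dim = 3,
    activation = "relu"
  )
  for (share in c(TRUE, FALSE)) {
    enc1 <- make_encoder(spec1, seed = 24, n_layers = 1L)
    set.seed(25)
    params <- c(enc1$params, list(W1 = glorot(3, 2)))
    if (!share) params$W1_sigma <- glorot(3, 2)
    worst <- grad_check(
      make_vgae_loss(spec1, X, gc, A_target, epsilon,
        pos_weight = 3, kl_scale = 0.1, share = share
      ),
      params
    )
    expect_lt(worst, 1e-6)
  }
})

test_that("gradients accumulate across node reuse", {
  tape <- ad_tape()
  x <- ad_param(tape, matrix(2, 1, 1))
  y <- ad_add(tape, x, x) # y = 2x
  loss <- ad_sum(tape, ad_mul(tape, y, y)) # (2x)^2, d/dx = 8x = 16
  ad_backward(tape, loss)
  expect_equal(x$grad[1, 1], 16)
})

test_that("segment softmax normalizes within segments and matches a direct computation", {
  tape <- ad_tape()
  e <- ad_const(tape, matrix(c(1, 2, 3, -1, 0), ncol = 1))
  groups <- c(1, 1, 2, 2, 2)
  y <- ad_segment_softmax(tape, e, groups)$value[, 1]
  expect_equal(sum(y[1:2]), 1)
  expect_equal(sum(y[3:5]), 1)
  expect_equal(y[1], exp(1) / (exp(1) + exp(2)))
  expect_equal(y[3], exp(3) / (exp(3) + exp(-1) + exp(0)))
})

test_that("one Adam step moves a parameter by about the learning rate against the gradient sign", {
  params <- list(w = matrix(2, 1, 1))
  grads <- list(w = matrix(5, 1, 1))
  st <- adam_init(params)
  out <- adam_step(st, params, grads, lr = 0.01)
  # bias-corrected first step: lr * g / (|g| + eps) ~ lr * sign(g)
  expect_equal(out$params$w[1, 1], 2 - 0.01, tolerance = 1e-6)
  expect_equal(out$state$t, 1L)
})
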