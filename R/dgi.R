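# Deep graph infomax: learn embeddings by discriminating true (feature,
# graph) pairs from corrupted ones. Corruption permutes feature rows while
# reusing the topology; a readout pools node embeddings into a global
# summary; a bilinear discriminator scores local-global pairs; the objective
# is a standard binary cross-entropy over positive and negative scores.

#' Corrupt a feature matrix for negative sampling
#'
#' Applies a seeded uniform-random row permutation to `X` and returns the
#' adjacency unchanged: negatives keep the true topology but carry the wrong
#' features.
#'
#' @param X Feature matrix.
#' @param A Adjacency (any object; returned as-is).
#' @param seed Integer seed.
#' @return List with `X_corrupt`, `A` (identical to the input), and the
#'   `permutation` used.
#' @export
corrupt <- function(X, A, seed = 0) {
  X <- as.matrix(X)
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(X))
  list(X_corrupt = X[perm, , drop = FALSE], A = A, permutation = perm)
}

#' Readout: global summary of node embeddings
#'
#' Component-wise logistic of the column means of `H` (the original deep
#' graph infomax readout).
#'
#' @param H n x d embedding matrix, n >= 1.
#' @return Summary vector of length d, entries in (0, 1).
#' @export
readout <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) == 0) stop("readout of an empty embedding", call. = FALSE)
  1 / (1 + exp(-colMeans(H)))
}

#' Bilinear discriminator score
#'
#' `logistic(h' W S)`: the probability that local embedding `h` belongs to
#' the graph summarized by `S`.
#'
#' @param h Local embedding (length-d vector or n x d matrix).
#' @param S Global summary vector (length d).
#' @param W d x d bilinear weight matrix.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
discriminate <- function(h, S, W) {
  h <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  as.vector(1 / (1 + exp(-(h %*% W %*% matrix(S, ncol = 1)))))
}

#' Deep graph infomax loss
#'
#' `-mean(log pos) - mean(log(1 - neg))`: the negation (to be minimized) of
#' the mutual-information lower bound, a binary cross-entropy with positives
#' labelled 1 and corrupted samples labelled 0. Scores at exactly 0 or 1 are
#' clamped at 1e-12 before the logarithm.
#'
#' @param pos_scores,neg_scores Probability vectors in (0, 1).
#' @return Non-negative scalar; equals `2 * log(2)` at uninformative scores
#'   of 0.5.
#' @export
dgi_loss <- function(pos_scores, neg_scores) {
  eps <- 1e-12
  p <- pmin(pmax(pos_scores, eps), 1 - eps)
  q <- pmin(pmax(neg_scores, eps), 1 - eps)
  -mean(log(p)) - mean(log(1 - q))
}

#' Train the deep graph infomax module
#'
#' Minimizes [dgi_loss()] with Adam; a fresh corruption is drawn each epoch
#' (configurable). The final embedding is the positive-branch encoder output
#' at the trained parameters (deterministic). Fully reproducible given
#' `cfg$seed`.
#'
#' @param fm A `feature_matrix` from [preprocess()], or a plain matrix.
#' @param g A `spatial_graph`.
#' @param spec An [encoder_spec()]; its activation is forced to the module's
#'   PReLU convention unless set explicitly.
#' @param cfg List: `epochs` (default 500), `lr` (default 1e-3), `seed`
#'   (default 0), `resample_corruption` (default TRUE).
#' @return List with `embedding` (an [embedding_matrix()]) and `state`
#'   (encoder, discriminator weight, per-epoch `train_log`, seed).
#' @export
train_dgi <- function(fm, g, spec, cfg = list()) {
  cfg <- utils::modifyList(
    list(epochs = 500L, lr = 1e-3, seed = 0L, resample_corruption = TRUE),
    cfg
  )
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  stopifnot(all(is.finite(X)))
  if (ncol(X) != spec$in_dim) {
    stop(sprintf(
      "feature matrix has %d columns but encoder expects in_dim = %d",
      ncol(X), spec$in_dim
    ), call. = FALSE)
  }
  enc <- make_encoder(spec, seed = cfg$seed, n_layers = 2L)
  d <- spec$out_dim
  set.seed(stage_seed(cfg$seed, "dgi_disc"))
  params <- c(enc$params, list(Wd = glorot(d, d)))
  gc <- graph_consts(g)
  opt <- adam_init(params)
  losses <- numeric(cfg$epochs)
  perm_seed <- stage_seed(cfg$seed, "dgi_corrupt")

  for (epoch in seq_len(cfg$epochs)) {
    seed_e <- if (isTRUE(cfg$resample_corruption)) perm_seed + epoch else perm_seed
    Xc <- corrupt(X, NULL, seed = seed_e)$X_corrupt
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_param(tape, p))
    enc_l <- list(spec = spec, n_layers = enc$n_layers)
    H <- ad_encoder_forward(tape, enc_l, pn, ad_const(tape, X), gc)
    Hc <- ad_encoder_forward(tape, enc_l, pn, ad_const(tape, Xc), gc)
    S <- ad_sigmoid(tape, ad_colmeans(tape, H)) # 1 x d
    Wd_S <- ad_matmul(tape, pn$Wd, ad_transpose(tape, S)) # d x 1
    pos <- ad_matmul(tape, H, Wd_S)
    neg <- ad_matmul(tape, Hc, Wd_S)
    loss <- ad_add(
      tape,
      ad_bce_logits(tape, pos, 1),
      ad_bce_logits(tape, neg, 0)
    )
    if (!is.finite(loss$value[1, 1])) {
      stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
    }
    losses[epoch] <- loss$value[1, 1]
    ad_backward(tape, loss)
    grads <- lapply(pn, function(nd) nd$grad)
    step <- adam_step(opt, params, grads, lr = cfg$lr)
    opt <- step$state
    params <- step$params
  }

  enc$params <- params[names(enc$params)]
  H_final <- encoder_embed(enc, X, g)
  spot_ids <- if (!is.null(rownames(X))) {
    rownames(X)
  } else {
    paste0("spot_", seq_len(nrow(X)) - 1L)
  }
  list(
    embedding = embedding_matrix(H_final, spot_ids,
      module_tag = "dgi", encoder_tag = spec$family
    ),
    state = structure(
      list(
        encoder = enc, discriminator_weight = params$Wd,
        train_log = losses, seed = cfg$seed, cfg = cfg
      ),
      class = "dgi_state"
    )
  )
}
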