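# Variational graph autoencoder: a two-layer graph encoder produces Gaussian
# posterior parameters per spot, a latent sample is drawn with the
# reparameterization trick, and the adjacency is reconstructed through an
# inner-product decoder. The loss is class-weighted reconstruction
# cross-entropy plus the Gaussian Kullback-Leibler divergence to the
# standard-normal prior.

#' Variational encoder forward pass
#'
#' First layer: `X_tilde = ReLU(A_norm X W0)`. Second layer: posterior heads
#' `mu = A_norm X_tilde W1` and `log sigma^2`. With `share_heads = TRUE` (the
#' default) the two heads share `W1`, so `mu` and `log sigma^2` are
#' element-wise identical; `share_heads = FALSE` uses a separate
#' `W1_sigma` (the conventional variational-autoencoder variant).
#'
#' @param X Feature matrix.
#' @param A_norm Symmetrically normalized adjacency (self loops included).
#' @param W0 First-layer weight (p x hidden).
#' @param W1 Head weight (hidden x latent).
#' @param W1_sigma Separate log-variance head, used when `share_heads = FALSE`.
#' @param share_heads Share `W1` between the two heads (default TRUE).
#' @return List with `mu`, `log_sigma2`, and the hidden `X_tilde`.
#' @export
vgae_encode <- function(X, A_norm, W0, W1, W1_sigma = NULL,
                        share_heads = TRUE) {
  X <- as.matrix(X)
  Xt <- pmax(as.matrix(A_norm %*% X) %*% W0, 0)
  AXt <- as.matrix(A_norm %*% Xt)
  mu <- AXt %*% W1
  log_sigma2 <- if (share_heads) mu else AXt %*% W1_sigma
  list(mu = mu, log_sigma2 = log_sigma2, X_tilde = Xt)
}

#' Reparameterization trick
#'
#' `Z = mu + exp(0.5 * log_sigma2) * epsilon` with `epsilon ~ N(0, 1)` drawn
#' from `seed`, or supplied explicitly for tests.
#'
#' @param mu,log_sigma2 Equal-shape matrices.
#' @param seed Integer seed for the noise draw.
#' @param epsilon Optional explicit noise matrix.
#' @return Latent matrix `Z`.
#' @export
reparameterize <- function(mu, log_sigma2, seed = 0, epsilon = NULL) {
  stopifnot(all(dim(mu) == dim(log_sigma2)))
  if (is.null(epsilon)) {
    set.seed(as.integer(seed))
    epsilon <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  mu + exp(0.5 * log_sigma2) * epsilon
}

#' Inner-product decoder
#'
#' `P = logistic(Z Z')`: symmetric matrix of edge probabilities in (0, 1).
#'
#' @param Z Latent matrix.
#' @return n x n probability matrix.
#' @export
decode_inner_product <- function(Z) {
  Z <- as.matrix(Z)
  logistic(tcrossprod(Z))
}

#' Variational graph autoencoder loss
#'
#' `recon` is the mean binary cross-entropy between the decoded edge
#' probabilities and the target adjacency (self loops counted as positives),
#' with the positive class weighted by `pos_weight` (default
#' `(n^2 - nnz) / nnz`, balancing the sparse edge class). `kl` is the
#' Gaussian divergence to the standard-normal prior, summed over latent
#' units and averaged over spots:
#' `kl = (1/n) sum 0.5 (exp(log_sigma2) + mu^2 - 1 - log_sigma2)`.
#' `total = recon + kl_scale * kl` with `kl_scale` defaulting to `1/n`.
#'
#' @param P Decoded probability matrix.
#' @param A_target Binary symmetric target adjacency (with self loops).
#' @param mu,log_sigma2 Posterior parameters.
#' @param pos_weight Positive-class weight; `NULL` computes the class-balance
#'   default.
#' @param kl_scale Weight of the divergence term; `NULL` gives `1/n`.
#' @return List with `total`, `recon`, `kl`.
#' @export
vgae_loss <- function(P, A_target, mu, log_sigma2, pos_weight = NULL,
                      kl_scale = NULL) {
  P <- as.matrix(P)
  A_target <- as.matrix(A_target)
  n <- nrow(P)
  nnz <- sum(A_target)
  if (is.null(pos_weight)) {
    pos_weight <- if (nnz > 0) (n^2 - nnz) / nnz else 1
  }
  if (is.null(kl_scale)) kl_scale <- 1 / n
  eps <- 1e-12
  Pc <- pmin(pmax(P, eps), 1 - eps)
  recon <- mean(-pos_weight * A_target * log(Pc) -
    (1 - A_target) * log(1 - Pc))
  kl <- sum(0.5 * (exp(log_sigma2) + mu^2 - 1 - log_sigma2)) / n
  list(total = recon + kl_scale * kl, recon = recon, kl = kl)
}

#' Train the variational graph autoencoder module
#'
#' Minimizes [vgae_loss()] with Adam, drawing one reparameterization sample
#' per epoch. The first-layer convolution is the chosen encoder family (a
#' GCN layer for `family = "gcn"`, otherwise that family's single
#' convolution with ReLU); the posterior heads are shared-weight by default.
#' The final embedding is the posterior mean `mu`, deterministic at
#' inference.
#'
#' @param fm A `feature_matrix` or plain matrix.
#' @param g A `spatial_graph` (build with self loops for the normalization).
#' @param spec An [encoder_spec()]; `hidden_dim` sizes the first layer and
#'   `out_dim` the latent space.
#' @param cfg List: `epochs` (default 500), `lr` (default 1e-3), `seed`
#'   (default 0), `share_heads` (default TRUE), `pos_weight` (NULL =
#'   class balance), `kl_scale` (NULL = 1/n).
#' @return List with `embedding` (the posterior mean) and `state`
#'   (parameters, per-epoch `train_log` with `total`/`recon`/`kl`, seed).
#' @export
train_vgae <- function(fm, g, spec, cfg = list()) {
  cfg <- utils::modifyList(
    list(
      epochs = 500L, lr = 1e-3, seed = 0L, share_heads = TRUE,
      pos_weight = NULL, kl_scale = NULL
    ),
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
  n <- nrow(X)
  # first layer: the family's single convolution, ReLU activation
  spec1 <- encoder_spec(spec$family,
    in_dim = spec$in_dim,
    hidden_dim = spec$hidden_dim, out_dim = spec$hidden_dim,
    hops_K = spec$hops_K, heads = spec$heads, activation = "relu"
  )
  enc1 <- make_encoder(spec1, seed = cfg$seed, n_layers = 1L)
  hidden_eff <- spec$hidden_dim *
    (if (spec$family == "gatv2") spec$heads else 1L)
  set.seed(stage_seed(cfg$seed, "vgae_heads"))
  params <- c(enc1$params, list(W1 = glorot(hidden_eff, spec$out_dim)))
  if (!isTRUE(cfg$share_heads)) {
    params$W1_sigma <- glorot(hidden_eff, spec$out_dim)
  }
  gc <- graph_consts(g)
  A_target <- as.matrix(g$A)
  diag(A_target) <- 1 # self loops are reconstruction positives
  nnz <- sum(A_target)
  pos_weight <- if (is.null(cfg$pos_weight)) (n^2 - nnz) / nnz else cfg$pos_weight
  kl_scale <- if (is.null(cfg$kl_scale)) 1 / n else cfg$kl_scale

  opt <- adam_init(params)
  log_total <- log_recon <- log_kl <- numeric(cfg$epochs)
  eps_seed <- stage_seed(cfg$seed, "vgae_eps")

  for (epoch in seq_len(cfg$epochs)) {
    set.seed(eps_seed + epoch)
    epsilon <- matrix(stats::rnorm(n * spec$out_dim), n, spec$out_dim)
    tape <- ad_tape()
    pn <- lapply(params, function(p) ad_param(tape, p))
    enc_l <- list(spec = spec1, n_layers = 1L)
    Xt <- ad_encoder_forward(tape, enc_l, pn, ad_const(tape, X), gc,
      final_linear = FALSE
    )
    AXt <- ad_spmm(tape, gc$An, Xt)
    mu <- ad_matmul(tape, AXt, pn$W1)
    log_s2 <- if (isTRUE(cfg$share_heads)) {
      mu
    } else {
      ad_matmul(tape, AXt, pn$W1_sigma)
    }
    sig <- ad_exp(tape, ad_scale(tape, log_s2, 0.5))
    Z <- ad_add(tape, mu, ad_mul(tape, sig, ad_const(tape, epsilon)))
    logits <- ad_tcrossprod(tape, Z)
    recon <- ad_bce_logits(tape, logits, A_target, pos_weight = pos_weight)
    # kl = sum(0.5 (exp(ls) + mu^2 - 1 - ls)) / n
    kl_terms <- ad_add(
      tape,
      ad_add(tape, ad_exp(tape, log_s2), ad_mul(tape, mu, mu)),
      ad_scale(tape, log_s2, -1)
    )
    kl <- ad_scale(
      tape,
      ad_sum(tape, kl_terms), 0.5 / n
    )
    kl_const <- -0.5 * length(mu$value) / n # the "-1" term, parameter-free
    loss <- ad_add(tape, recon, ad_scale(tape, kl, kl_scale))
    total_val <- loss$value[1, 1] + kl_scale * kl_const
    if (!is.finite(total_val)) {
      stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
    }
    log_total[epoch] <- total_val
    log_recon[epoch] <- recon$value[1, 1]
    log_kl[epoch] <- kl$value[1, 1] + kl_const
    ad_backward(tape, loss)
    grads <- lapply(pn, function(nd) nd$grad)
    step <- adam_step(opt, params, grads, lr = cfg$lr)
    opt <- step$state
    params <- step$params
  }

  enc1$params <- params[names(enc1$params)]
  Xt_fin <- encoder_embed(enc1, X, g, final_linear = FALSE)
  AXt_fin <- as.matrix(gc$An %*% Xt_fin)
  mu_fin <- AXt_fin %*% params$W1
  ls_fin <- if (isTRUE(cfg$share_heads)) mu_fin else AXt_fin %*% params$W1_sigma
  spot_ids <- if (!is.null(rownames(X))) {
    rownames(X)
  } else {
    paste0("spot_", seq_len(n) - 1L)
  }
  list(
    embedding = embedding_matrix(mu_fin, spot_ids,
      module_tag = "vgae", encoder_tag = spec$family
    ),
    state = structure(
      list(
        encoder_first = enc1, head_weight = params$W1,
        head_weight_sigma = params$W1_sigma,
        mu = mu_fin, log_sigma2 = ls_fin,
        train_log = data.frame(
          epoch = seq_len(cfg$epochs),
          total = log_total, recon = log_recon, kl = log_kl
        ),
        seed = cfg$seed, cfg = cfg
      ),
      class = "vgae_state"
    )
  )
}
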