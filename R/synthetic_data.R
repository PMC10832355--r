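# Synthetic spatial omics generator: layered (cortex-like) or blob-like
# domain geometries with domain-specific expression programs, so every stage
# of the pipeline is testable without external downloads.

#' Configuration for the synthetic-tissue generator
#'
#' @param n_spots Number of spots (default 800).
#' @param n_genes Number of features (default 200).
#' @param n_domains Number of spatial domains, at least 2 (default 5).
#' @param geometry `"layers"` (horizontal bands on a jittered grid, the
#'   layered-cortex geometry) or `"blobs"` (Gaussian scatter around random
#'   centers, the imaging-data geometry).
#' @param signal_strength Mean log-scale shift of each domain's gene program,
#'   in units of `noise_sd` (default 3).
#' @param program_size Genes elevated per domain (default 40); programs are
#'   disjoint, so `program_size * n_domains` may not exceed `n_genes`.
#' @param noise_sd Log-scale Gaussian noise standard deviation (default 1).
#' @param dropout_rate Probability that an observed entry is zeroed
#'   (default 0).
#' @param seed Integer seed (default 0).
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_spots = 800, n_genes = 200, n_domains = 5,
                             geometry = c("layers", "blobs"),
                             signal_strength = 3, program_size = 40,
                             noise_sd = 1, dropout_rate = 0, seed = 0) {
  geometry <- match.arg(geometry)
  if (n_domains < 2) stop("n_domains must be at least 2", call. = FALSE)
  if (program_size * n_domains > n_genes) {
    stop(sprintf(
      "program_size * n_domains = %d exceeds n_genes = %d",
      program_size * n_domains, n_genes
    ), call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (signal_strength < 0 || noise_sd <= 0) {
    stop("signal_strength must be >= 0 and noise_sd > 0", call. = FALSE)
  }
  structure(
    list(
      n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
      n_domains = as.integer(n_domains), geometry = geometry,
      signal_strength = signal_strength,
      program_size = as.integer(program_size), noise_sd = noise_sd,
      dropout_rate = dropout_rate, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Balanced contiguous assignment: sorts values and cuts into m chunks whose
# sizes differ by at most one.
balanced_bands <- function(values, m) {
  n <- length(values)
  sizes <- rep(n %/% m, m) + c(rep(1L, n %% m), rep(0L, m - n %% m))
  bands <- integer(n)
  bands[order(values)] <- rep.int(seq_len(m), sizes)
  bands
}

#' Generate a synthetic spatial omics dataset
#'
#' `layers` geometry places spots on a jittered square grid in the unit
#' square and assigns domains as contiguous horizontal bands of (nearly)
#' equal occupancy. `blobs` geometry samples domain centers uniformly and
#' scatters spots around them, labelling each spot by its nearest center.
#' Expression is lognormal: a per-gene baseline plus the domain's program
#' shift (`signal_strength * noise_sd` on the log scale) plus Gaussian log
#' noise, exponentiated, then subjected to multiplicative Bernoulli dropout.
#' Fully seeded and reproducible.
#'
#' @param cfg A [synthetic_config()].
#' @return A [spatial_dataset()] with `labels` set to the true domains.
#' @export
generate_spatial_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_spots
  m <- cfg$n_domains

  if (cfg$geometry == "layers") {
    side <- ceiling(sqrt(n))
    gx <- ((seq_len(n) - 1L) %% side + 0.5) / side
    gy <- ((seq_len(n) - 1L) %/% side + 0.5) / side
    spacing <- 1 / side
    coords <- cbind(
      x = gx + stats::rnorm(n, 0, 0.25 * spacing),
      y = gy + stats::rnorm(n, 0, 0.25 * spacing)
    )
    labels <- balanced_bands(gy + 1e-9 * seq_len(n), m) # grid bands, balanced
  } else {
    centers <- cbind(stats::runif(m), stats::runif(m))
    assign0 <- rep.int(seq_len(m), ceiling(n / m))[seq_len(n)]
    coords <- centers[assign0, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, 0, 0.08), n, 2)
    colnames(coords) <- c("x", "y")
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * coords %*% t(centers)
    labels <- max.col(-d2, ties.method = "first")
  }

  base <- stats::rnorm(cfg$n_genes, 0, 0.5)
  shift <- cfg$signal_strength * cfg$noise_sd
  programs <- split(
    seq_len(cfg$program_size * m),
    rep(seq_len(m), each = cfg$program_size)
  )
  logx <- matrix(base,
    nrow = n, ncol = cfg$n_genes, byrow = TRUE
  ) + matrix(stats::rnorm(n * cfg$n_genes, 0, cfg$noise_sd), n, cfg$n_genes)
  for (dmn in seq_len(m)) {
    rows <- labels == dmn
    logx[rows, programs[[dmn]]] <- logx[rows, programs[[dmn]]] + shift
  }
  expr <- exp(logx)
  if (cfg$dropout_rate > 0) {
    keep <- matrix(
      stats::rbinom(n * cfg$n_genes, 1, 1 - cfg$dropout_rate),
      n, cfg$n_genes
    )
    expr <- expr * keep
  }
  spatial_dataset(expr, coords,
    labels = labels,
    feature_names = paste0("gene_", seq_len(cfg$n_genes)),
    spot_ids = paste0("spot_", seq_len(n) - 1L)
  )
}

#' Expected separability of a synthetic configuration
#'
#' A monotone difficulty score: the between-domain mean shift in units of
#' the effective noise scale,
#' `signal_strength / sqrt(1 + dropout_rate / (1 - dropout_rate))`.
#' Equals `signal_strength` without dropout and strictly decreases as
#' dropout grows (dropout inflates the effective observation noise).
#'
#' @param cfg A [synthetic_config()].
#' @return Non-negative scalar.
#' @export
expected_separability <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  vi <- cfg$dropout_rate / (1 - cfg$dropout_rate)
  cfg$signal_strength / sqrt(1 + vi)
}

#' Preset synthetic configurations mirroring common platform shapes
#'
#' `dlpfc-like` (sequencing spots over cortical layers): 3600 spots, 3000
#' genes, 7 layered domains. `merfish-like` (imaging, small gene panel):
#' 13800 spots, 347 genes, 28 blob domains. `4i-like` (protein panel):
#' 16700 spots, 43 proteins, 10 blob domains. `scale` shrinks spot counts
#' (and caps feature/domain counts) for desk-scale runs.
#'
#' @param preset One of `"dlpfc-like"`, `"merfish-like"`, `"4i-like"`.
#' @param scale Multiplier on the spot count, in (0, 1] (default 1).
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("dlpfc-like", "merfish-like", "4i-like"),
                             scale = 1, seed = 0) {
  preset <- match.arg(preset)
  stopifnot(scale > 0, scale <= 1)
  base <- switch(preset,
    "dlpfc-like" = list(n = 3600, p = 3000, m = 7, geom = "layers"),
    "merfish-like" = list(n = 13800, p = 347, m = 28, geom = "blobs"),
    "4i-like" = list(n = 16700, p = 43, m = 10, geom = "blobs")
  )
  n <- max(50L, as.integer(round(base$n * scale)))
  m <- min(base$m, max(2L, n %/% 25L))
  prog <- max(1L, min(base$p %/% m, 40L))
  synthetic_config(
    n_spots = n, n_genes = base$p, n_domains = m,
    geometry = base$geom, program_size = prog, seed = seed
  )
}
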