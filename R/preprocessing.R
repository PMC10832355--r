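# Feature-matrix construction: library-size normalization -> log1p -> highly
# variable gene selection by normalized dispersion -> optional z-scoring.
# Both graph deep learning modules consume the resulting matrix X.

lognorm <- function(expression) {
  expr <- as.matrix(expression)
  totals <- rowSums(expr)
  target <- stats::median(totals[totals > 0])
  if (!is.finite(target) || target <= 0) target <- 1
  scaled <- expr
  pos <- totals > 0
  scaled[pos, ] <- expr[pos, , drop = FALSE] * (target / totals[pos])
  if (any(!pos)) {
    warning(sprintf(
      "%d spot(s) with zero total count: normalized rows set to zero",
      sum(!pos)
    ), call. = FALSE)
    scaled[!pos, ] <- 0
  }
  log1p(scaled)
}

#' Select highly variable features
#'
#' Ranks features by normalized dispersion (variance/mean of the
#' library-size-normalized, log-transformed data) and returns the indices of
#' the top `n_top`. Ties are broken by ascending original column index; when
#' `n_top` is at least the number of features, all features are returned in
#' their original order (the behavior used for small protein panels, where
#' every feature enters the model).
#'
#' @param expression Non-negative matrix, spots x features.
#' @param n_top Number of features to keep (default 3000).
#' @return Integer vector of column indices.
#' @export
select_hvgs <- function(expression, n_top = 3000) {
  stopifnot(n_top >= 1)
  expr <- as.matrix(expression)
  if (all(expr == 0)) stop("no variable features: expression is all zero", call. = FALSE)
  p <- ncol(expr)
  if (n_top >= p) {
    return(seq_len(p))
  }
  ln <- suppressWarnings(lognorm(expr))
  mu <- colMeans(ln)
  v <- apply(ln, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, seq_len(p))
  sort(ord[seq_len(n_top)])
}

#' Build the normalized feature matrix
#'
#' Library-size normalizes each spot to the median total count, applies
#' `log(1 + x)`, keeps the `hvg_index` columns, and optionally z-scores each
#' feature (constant features are left at zero: their standard deviation is
#' guarded at 1). Spots with zero total count yield all-zero rows and a
#' warning rather than an error. The pipeline is deterministic.
#'
#' @param expression Non-negative matrix, spots x features.
#' @param hvg_index Integer vector of feature columns to keep.
#' @param standardize Z-score features after the log transform (default TRUE).
#' @return A `feature_matrix` object: `X` (spots x HVGs), `hvg_index`, and
#'   `scaling_stats` (per-feature mean/sd used).
#' @export
normalize_features <- function(expression, hvg_index, standardize = TRUE) {
  expr <- as.matrix(expression)
  if (any(hvg_index < 1 | hvg_index > ncol(expr))) {
    stop("hvg_index out of range", call. = FALSE)
  }
  X <- lognorm(expr)[, hvg_index, drop = FALSE]
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (nrow(X) < 2) sd <- rep(0, ncol(X))
  sd_guarded <- ifelse(is.na(sd) | sd < 1e-12, 1, sd)
  if (standardize) {
    X <- sweep(sweep(X, 2, mu, "-"), 2, sd_guarded, "/")
  }
  structure(
    list(
      X = X, hvg_index = as.integer(hvg_index),
      scaling_stats = list(mean = mu, sd = sd_guarded),
      standardized = standardize
    ),
    class = "feature_matrix"
  )
}

#' Preprocess a spatial dataset into model features
#'
#' Convenience wrapper: selects highly variable features and normalizes them.
#' Small panels (protein data with at most `small_panel_threshold` features)
#' skip the variable-feature screen and use every feature, matching how
#' image-based panels with few hundred or fewer targets are handled.
#'
#' @param ds A [spatial_dataset()].
#' @param n_hvg Number of highly variable features to keep (default 3000).
#' @param standardize Z-score features (default TRUE).
#' @param small_panel_threshold Panels with at most this many features skip
#'   selection entirely (default 50).
#' @return A `feature_matrix`.
#' @export
preprocess <- function(ds, n_hvg = 3000, standardize = TRUE,
                       small_panel_threshold = 50) {
  expr <- as.matrix(ds$expression)
  idx <- if (ncol(expr) <= small_panel_threshold) {
    seq_len(ncol(expr))
  } else {
    select_hvgs(expr, n_top = n_hvg)
  }
  normalize_features(expr, idx, standardize = standardize)
}
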