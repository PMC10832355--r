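# Spot-spot neighbor graph from 2-D coordinates, plus the symmetric
# normalization D^(-1/2) A D^(-1/2) every convolutional encoder consumes.

#' Symmetrically normalize an adjacency matrix
#'
#' Computes `D^(-1/2) (A + I*self_loops) D^(-1/2)` where `D` is the diagonal
#' degree matrix of the (optionally self-looped) adjacency. Zero-degree rows
#' map to zero rows rather than dividing by zero.
#'
#' @param A Symmetric non-negative (sparse or dense) matrix.
#' @param self_loops Add the identity before normalizing (default FALSE).
#' @return A sparse symmetric matrix.
#' @export
normalize_adjacency <- function(A, self_loops = FALSE) {
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  if (!Matrix::isSymmetric(A, tol = 0)) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (self_loops) A <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dh <- Matrix::Diagonal(x = dinv)
  methods::as(Dh %*% A %*% Dh, "CsparseMatrix")
}

#' Build a spatial neighbor graph
#'
#' `knn` mode connects each spot to its `k` nearest Euclidean neighbors and
#' symmetrizes by union (an edge is kept if either endpoint selected it), so
#' no spot is isolated by one-sided selection. `radius` mode connects every
#' pair at distance at most `radius`. Exact distance ties are broken by
#' ascending spot index; duplicate coordinates are allowed. With
#' `self_loops = TRUE` (the default, the graph-convolution convention) the
#' identity is added to the adjacency before normalization.
#'
#' @param coords Numeric matrix, `n x 2`.
#' @param mode `"knn"` or `"radius"`.
#' @param k Number of neighbors (knn mode, default 6 - suited to hexagonal
#'   spot grids).
#' @param radius Distance cutoff (radius mode), in the coordinates' own unit.
#' @param self_loops Include self edges (default TRUE).
#' @param block Internal row-block size for the distance computation.
#' @return A `spatial_graph` object with fields `A` (binary sparse symmetric
#'   adjacency), `A_norm` (its symmetric normalization), `degree`, and
#'   `params` (the construction record).
#' @export
build_graph <- function(coords, mode = c("knn", "radius"), k = 6,
                        radius = NULL, self_loops = TRUE, block = 1024L) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 2, ncol(coords) == 2)
  if (mode == "knn" && k >= n) {
    stop(sprintf("k = %d must be smaller than the number of spots (%d)", k, n),
      call. = FALSE
    )
  }
  if (mode == "radius" && (is.null(radius) || radius <= 0)) {
    stop("radius mode requires a positive radius", call. = FALSE)
  }
  ii <- integer(0)
  jj <- integer(0)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared Euclidean distances, rows x all
    d2 <- outer(sq[rows], sq, "+") -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    d2 <- pmax(d2, 0)
    if (mode == "knn") {
      for (r in seq_along(rows)) {
        i <- rows[r]
        dr <- d2[r, ]
        dr[i] <- Inf # never select self
        nb <- order(dr, seq_len(n))[seq_len(k)]
        ii <- c(ii, rep.int(i, k))
        jj <- c(jj, nb)
      }
    } else {
      hit <- which(d2 <= radius^2, arr.ind = TRUE)
      keep <- rows[hit[, 1]] != hit[, 2]
      ii <- c(ii, rows[hit[keep, 1]])
      jj <- c(jj, hit[keep, 2])
    }
  }
  A <- Matrix::sparseMatrix(
    i = ii, j = jj, x = 1, dims = c(n, n),
    use.last.ij = TRUE
  )
  A <- methods::as((A + Matrix::t(A)) > 0, "dMatrix") * 1 # union symmetrize
  if (sum(A) == 0) {
    warning("graph is edgeless at the chosen parameters", call. = FALSE)
  }
  if (self_loops) A <- methods::as((A + Matrix::Diagonal(n)) > 0, "dMatrix") * 1
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  structure(
    list(
      A = A,
      A_norm = normalize_adjacency(A, self_loops = FALSE),
      degree = as.integer(Matrix::rowSums(A)),
      params = list(
        mode = mode, k = if (mode == "knn") k else NULL,
        radius = if (mode == "radius") radius else NULL,
        self_loops = self_loops
      )
    ),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf(
    "<spatial_graph> %d spots, %d undirected edges (%s mode%s)\n",
    nrow(x$A), sum(x$A) %/% 2, x$params$mode,
    if (isTRUE(x$params$self_loops)) ", self loops" else ""
  ))
  invisible(x)
}

# Structural (off-diagonal) adjacency: neighbor sets for aggregation-style
# encoders exclude the self edge even when the stored A carries one.
graph_offdiag <- function(g) {
  A <- g$A
  Matrix::diag(A) <- 0
  Matrix::drop0(A)
}

# Row-normalized adjacency D^-1 A over structural neighbors (mean aggregation);
# isolated spots keep zero rows.
graph_rownorm <- function(g) {
  A <- graph_offdiag(g)
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / d, 0)
  methods::as(Matrix::Diagonal(x = dinv) %*% A, "CsparseMatrix")
}

# Directed edge list (src -> dst) over structural neighbors plus self edges,
# as used by attention aggregation.
graph_edges_with_self <- function(g) {
  A <- graph_offdiag(g)
  trip <- Matrix::summary(A)
  n <- nrow(A)
  list(
    src = c(trip$j, seq_len(n)), # message from j into i
    dst = c(trip$i, seq_len(n))
  )
}

#' Export the edge list of a spatial graph
#'
#' Writes a TSV with columns `i`, `j`, `weight` (one row per directed edge of
#' the stored adjacency) for external inspection.
#'
#' @param g A `spatial_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_edges <- function(g, path) {
  trip <- Matrix::summary(methods::as(g$A, "CsparseMatrix"))
  utils::write.table(
    data.frame(i = trip$i, j = trip$j, weight = trip$x),
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
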