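#' Construct a spatial omics dataset
#'
#' The central container of the package: one expression vector and one 2-D
#' coordinate per spot (a cell, pixel, or sequencing spot, depending on the
#' platform), with optional ground-truth domain labels used only for scoring.
#'
#' @param expression Non-negative numeric matrix, spots in rows and features
#'   (genes or proteins) in columns. A sparse `Matrix` is accepted and kept
#'   sparse; densification happens lazily at preprocessing.
#' @param coordinates Numeric matrix with `n_spots` rows and 2 columns `(x, y)`,
#'   in the dataset's native length unit (no unit conversion is performed).
#' @param labels Optional integer vector of ground-truth domain labels, one per
#'   spot, with at least one distinct value.
#' @param feature_names Character vector of feature names; defaults to
#'   `feature_1..feature_p`.
#' @param spot_ids Character vector of unique spot identifiers; defaults to
#'   `spot_0..spot_{n-1}`.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expression, coordinates, labels = NULL,
                            feature_names = NULL, spot_ids = NULL) {
  if (!methods::is(expression, "Matrix")) {
    expression <- as.matrix(expression)
  }
  coordinates <- as.matrix(coordinates)
  n <- nrow(expression)
  p <- ncol(expression)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n) - 1L)
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(p))
  ds <- structure(
    list(
      expression = expression,
      coordinates = coordinates,
      labels = if (is.null(labels)) NULL else as.integer(labels),
      feature_names = as.character(feature_names),
      spot_ids = as.character(spot_ids)
    ),
    class = "spatial_dataset"
  )
  validate_spatial_dataset(ds)
  ds
}

validate_spatial_dataset <- function(ds) {
  n <- nrow(ds$expression)
  if (nrow(ds$coordinates) != n) {
    stop(sprintf(
      "expression has %d rows but coordinates has %d: spot counts must align",
      n, nrow(ds$coordinates)
    ), call. = FALSE)
  }
  if (ncol(ds$coordinates) != 2L) {
    stop("coordinates must have exactly 2 columns (x, y)", call. = FALSE)
  }
  if (length(ds$spot_ids) != n) {
    stop(sprintf(
      "expression has %d rows but spot_ids has length %d",
      n, length(ds$spot_ids)
    ), call. = FALSE)
  }
  if (anyDuplicated(ds$spot_ids)) {
    stop("duplicated spot_ids are not allowed", call. = FALSE)
  }
  if (length(ds$feature_names) != ncol(ds$expression)) {
    stop("feature_names length must match the number of expression columns",
      call. = FALSE
    )
  }
  if (any(!is.finite(ds$coordinates))) {
    stop("coordinates contain non-finite values", call. = FALSE)
  }
  mn <- if (methods::is(ds$expression, "Matrix")) {
    min(ds$expression@x, 0)
  } else {
    min(ds$expression)
  }
  if (is.finite(mn) && mn < 0) {
    stop("expression contains negative entries", call. = FALSE)
  }
  if (!is.null(ds$labels)) {
    if (length(ds$labels) != n) {
      stop(sprintf(
        "labels has length %d but the dataset has %d spots",
        length(ds$labels), n
      ), call. = FALSE)
    }
    if (length(unique(ds$labels)) < 1L) {
      stop("labels must contain at least one distinct value", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf(
    "<spatial_dataset> %d spots x %d features%s\n",
    nrow(x$expression), ncol(x$expression),
    if (is.null(x$labels)) {
      ""
    } else {
      sprintf(", %d labelled domains", length(unique(x$labels)))
    }
  ))
  invisible(x)
}

#' Construct an embedding matrix
#'
#' Holds the latent representation produced by a trained graph deep learning
#' module, aligned row-by-row with the source dataset's spots.
#'
#' @param values Numeric matrix, `n_spots` rows by `d_latent` columns; all
#'   entries must be finite.
#' @param spot_ids Character vector aligned to the source dataset.
#' @param module_tag `"dgi"` or `"vgae"`.
#' @param encoder_tag Encoder family name (see [encoder_families()]).
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, spot_ids, module_tag, encoder_tag) {
  values <- as.matrix(values)
  if (nrow(values) != length(spot_ids)) {
    stop("embedding row count must match spot_ids length", call. = FALSE)
  }
  if (length(values) > 0 && any(!is.finite(values))) {
    stop("embedding contains non-finite values", call. = FALSE)
  }
  if (!module_tag %in% c("dgi", "vgae")) {
    stop("module_tag must be 'dgi' or 'vgae'", call. = FALSE)
  }
  structure(
    list(
      values = values, spot_ids = as.character(spot_ids),
      module_tag = module_tag, encoder_tag = encoder_tag
    ),
    class = "embedding_matrix"
  )
}

#' Read a spatial dataset from disk
#'
#' Three dialects are supported. `csv`: a directory with `expression.csv`
#' (header row of feature names, first column of spot ids), `coordinates.csv`
#' (columns `spot_id,x,y`) and optionally `labels.csv` (`spot_id,label`).
#' `mtx`: a directory with a MatrixMarket triplet in the 10X convention
#' (`matrix.mtx` features x spots, `barcodes.tsv`, `features.tsv`) plus the
#' same `coordinates.csv`/`labels.csv`. `h5ad`: a single AnnData file whose
#' `obsm` carries the coordinates under a spatial slot; this dialect is
#' converted through the `python` interpreter's `anndata` package.
#'
#' @param path Directory (`csv`, `mtx`) or file (`h5ad`).
#' @param format One of `"csv"`, `"mtx"`, `"h5ad"`.
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(path, format = c("csv", "mtx", "h5ad")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop(sprintf("unknown format '%s': use one of csv, mtx, h5ad", format[1]),
      call. = FALSE
    )
  })
  switch(format,
    csv = read_dataset_csv(path),
    mtx = read_dataset_mtx(path),
    h5ad = read_dataset_h5ad(path)
  )
}

read_coords_labels <- function(path, spot_ids) {
  cf <- file.path(path, "coordinates.csv")
  if (!file.exists(cf)) stop(sprintf("missing %s", cf), call. = FALSE)
  co <- utils::read.csv(cf, stringsAsFactors = FALSE)
  coords <- as.matrix(co[, c("x", "y")])
  if (!is.null(co$spot_id) && !is.null(spot_ids)) {
    if (nrow(co) == length(spot_ids)) {
      coords <- coords[match(spot_ids, co$spot_id), , drop = FALSE]
    }
  }
  labels <- NULL
  lf <- file.path(path, "labels.csv")
  if (file.exists(lf)) {
    lb <- utils::read.csv(lf, stringsAsFactors = FALSE)
    labels <- lb$label
    if (!is.null(lb$spot_id) && !is.null(spot_ids) &&
      nrow(lb) == length(spot_ids)) {
      labels <- lb$label[match(spot_ids, lb$spot_id)]
    }
  }
  list(coordinates = coords, labels = labels)
}

read_dataset_csv <- function(path) {
  ef <- file.path(path, "expression.csv")
  if (!file.exists(ef)) stop(sprintf("missing %s", ef), call. = FALSE)
  ex <- utils::read.csv(ef, row.names = 1, check.names = FALSE)
  expr <- as.matrix(ex)
  cl <- read_coords_labels(path, rownames(expr))
  spatial_dataset(expr, cl$coordinates,
    labels = cl$labels,
    feature_names = colnames(expr), spot_ids = rownames(expr)
  )
}

read_dataset_mtx <- function(path) {
  mf <- file.path(path, "matrix.mtx")
  if (!file.exists(mf)) stop(sprintf("missing %s", mf), call. = FALSE)
  m <- Matrix::readMM(mf) # features x spots, 10X convention
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  features <- readLines(file.path(path, "features.tsv"))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "matrix.mtx is %d x %d but features/barcodes have lengths %d/%d",
      nrow(m), ncol(m), length(features), length(barcodes)
    ), call. = FALSE)
  }
  expr <- Matrix::t(m)
  cl <- read_coords_labels(path, barcodes)
  spatial_dataset(expr, cl$coordinates,
    labels = cl$labels,
    feature_names = features, spot_ids = barcodes
  )
}

read_dataset_h5ad <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing %s", path), call. = FALSE)
  py <- Sys.which("python")
  if (py == "") {
    stop("h5ad support requires a 'python' interpreter with anndata",
      call. = FALSE
    )
  }
  script <- system.file("python", "h5ad_io.py", package = "spadom")
  tmp <- tempfile("h5ad_export_")
  dir.create(tmp)
  status <- system2(py, c(script, "export", shQuote(path), shQuote(tmp)),
    stdout = TRUE, stderr = TRUE
  )
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop(sprintf(
      "h5ad conversion failed for %s:\n%s",
      path, paste(status, collapse = "\n")
    ), call. = FALSE)
  }
  on.exit(unlink(tmp, recursive = TRUE))
  read_dataset_csv(tmp)
}

#' Write a spatial dataset to disk
#'
#' Emits the file layout [read_dataset()] expects; a write/read round trip
#' preserves all fields (values within 1e-9). When the dataset has no labels,
#' no labels file is written.
#'
#' @param ds A [spatial_dataset()].
#' @param path Output directory (`csv`, `mtx`) or `.h5ad` file path.
#' @param format One of `"csv"`, `"mtx"`, `"h5ad"`.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, path, format = c("csv", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (format %in% c("csv", "mtx")) {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("cannot create directory '%s'", path), call. = FALSE)
    }
  }
  written <- switch(format,
    csv = write_dataset_csv(ds, path),
    mtx = write_dataset_mtx(ds, path),
    h5ad = write_dataset_h5ad(ds, path)
  )
  invisible(written)
}

write_coords_labels <- function(ds, path) {
  cf <- file.path(path, "coordinates.csv")
  utils::write.csv(
    data.frame(
      spot_id = ds$spot_ids,
      x = ds$coordinates[, 1], y = ds$coordinates[, 2]
    ),
    cf,
    row.names = FALSE
  )
  files <- cf
  if (!is.null(ds$labels)) {
    lf <- file.path(path, "labels.csv")
    utils::write.csv(data.frame(spot_id = ds$spot_ids, label = ds$labels),
      lf,
      row.names = FALSE
    )
    files <- c(files, lf)
  }
  files
}

write_dataset_csv <- function(ds, path) {
  ef <- file.path(path, "expression.csv")
  expr <- as.matrix(ds$expression)
  dimnames(expr) <- list(ds$spot_ids, ds$feature_names)
  utils::write.csv(expr, ef, row.names = TRUE)
  c(ef, write_coords_labels(ds, path))
}

write_dataset_mtx <- function(ds, path) {
  mf <- file.path(path, "matrix.mtx")
  m <- methods::as(
    methods::as(Matrix::t(Matrix::Matrix(ds$expression, sparse = TRUE)), "generalMatrix"),
    "CsparseMatrix"
  )
  Matrix::writeMM(m, mf)
  writeLines(ds$spot_ids, file.path(path, "barcodes.tsv"))
  writeLines(ds$feature_names, file.path(path, "features.tsv"))
  c(
    mf, file.path(path, c("barcodes.tsv", "features.tsv")),
    write_coords_labels(ds, path)
  )
}

write_dataset_h5ad <- function(ds, path) {
  py <- Sys.which("python")
  if (py == "") {
    stop("h5ad support requires a 'python' interpreter with anndata",
      call. = FALSE
    )
  }
  tmp <- tempfile("h5ad_import_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write_dataset_csv(ds, tmp)
  script <- system.file("python", "h5ad_io.py", package = "spadom")
  status <- system2(py, c(script, "import", shQuote(tmp), shQuote(path)),
    stdout = TRUE, stderr = TRUE
  )
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop(sprintf(
      "h5ad conversion failed for %s:\n%s",
      path, paste(status, collapse = "\n")
    ), call. = FALSE)
  }
  path
}

#' Write an embedding matrix as delimited text
#'
#' Tab-separated, one row per spot; the header names the latent columns
#' `<module_tag>.<encoder_tag>_1..d` so the provenance of the embedding
#' survives the round trip through [read_embeddings()].
#'
#' @param emb An [embedding_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(emb, path) {
  d <- ncol(emb$values)
  header <- c("spot_id", if (d > 0) {
    paste0(emb$module_tag, ".", emb$encoder_tag, "_", seq_len(d))
  })
  lines <- paste(header, collapse = "\t")
  if (nrow(emb$values) > 0) {
    body <- apply(
      cbind(emb$spot_ids, format(emb$values, digits = 15, trim = TRUE)),
      1, paste,
      collapse = "\t"
    )
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an embedding matrix written by [write_embeddings()]
#'
#' @param path File path.
#' @return An [embedding_matrix()].
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2) {
    tags <- c("dgi", "unknown")
    vals <- matrix(0, nrow(df), 0)
  } else {
    first <- colnames(df)[2]
    tags <- strsplit(sub("_[0-9]+$", "", first), ".", fixed = TRUE)[[1]]
    vals <- as.matrix(df[, -1, drop = FALSE])
  }
  embedding_matrix(vals, as.character(df[[1]]),
    module_tag = tags[1],
    encoder_tag = paste(tags[-1], collapse = ".")
  )
}
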