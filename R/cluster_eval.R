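# Clustering of latent embeddings into spatial domains, chance-corrected
# scoring (ARI/NMI), and accuracy/efficiency ranking of module x encoder
# combinations.

#' Cluster an embedding into spatial domains
#'
#' `gmm`: Gaussian mixture with `k` components fitted to the embedding
#' (projected onto its leading principal components when wider than
#' `pca_dim`, which stabilizes full-covariance fits), hard assignment by
#' maximum posterior. `leiden`: community detection on a k-nearest-neighbor
#' graph of the embedding at the given `resolution`. Both are deterministic
#' given `seed`.
#'
#' @param emb An [embedding_matrix()] or plain matrix.
#' @param k Number of domains (gmm mode; must be at least 2 and at most the
#'   number of spots).
#' @param method `"gmm"` or `"leiden"`.
#' @param resolution Leiden resolution (default 1).
#' @param seed Integer seed.
#' @param pca_dim Project to this many principal components first when the
#'   embedding is wider (default 20); `Inf` disables projection.
#' @param graph_k Neighbors for the Leiden embedding graph (default 15).
#' @return Integer label vector.
#' @export
cluster_embeddings <- function(emb, k = NULL, method = c("gmm", "leiden"),
                               resolution = 1, seed = 0, pca_dim = 20,
                               graph_k = 15) {
  method <- match.arg(method)
  V <- if (inherits(emb, "embedding_matrix")) emb$values else as.matrix(emb)
  n <- nrow(V)
  if (is.finite(pca_dim) && ncol(V) > pca_dim) {
    V <- stats::prcomp(V, center = TRUE, scale. = FALSE)$x[,
      seq_len(min(pca_dim, ncol(V))),
      drop = FALSE
    ]
  }
  if (method == "gmm") {
    stopifnot(!is.null(k), k >= 1)
    if (k > n) {
      stop(sprintf("k = %d exceeds the number of spots (%d)", k, n),
        call. = FALSE
      )
    }
    if (k == 1) {
      return(rep(1L, n))
    }
    set.seed(as.integer(seed))
    fit <- NULL
    for (model in c("VVV", "EEE", "EII")) {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(V,
          G = k, modelNames = model,
          verbose = FALSE
        )),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      set.seed(as.integer(seed))
      return(as.integer(
        stats::kmeans(V, centers = k, nstart = 10, iter.max = 100)$cluster
      ))
    }
    return(as.integer(fit$classification))
  }
  # leiden on a kNN graph of the embedding
  adj <- knn_adjacency(V, k = min(graph_k, n - 1))
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(ig,
    objective_function = "modularity",
    resolution = resolution
  )
  as.integer(igraph::membership(cl))
}

# kNN adjacency in arbitrary dimension (union-symmetrized, binary).
knn_adjacency <- function(V, k, block = 1024L) {
  n <- nrow(V)
  sq <- rowSums(V^2)
  ii <- integer(0)
  jj <- integer(0)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * V[rows, , drop = FALSE] %*% t(V)
    for (r in seq_along(rows)) {
      i <- rows[r]
      dr <- d2[r, ]
      dr[i] <- Inf
      nb <- order(dr, seq_len(n))[seq_len(k)]
      ii <- c(ii, rep.int(i, k))
      jj <- c(jj, nb)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  methods::as((A + Matrix::t(A)) > 0, "dMatrix") * 1
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, from the contingency
#' table: `(sum C(n_ij,2) - E) / (0.5 (sum C(a_i,2) + sum C(b_j,2)) - E)`
#' where `E` is the permutation-model expectation. 1 for identical
#' partitions, about 0 for independent ones; invariant to label renaming.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop(sprintf(
      "label vectors differ in length: %d vs %d",
      length(labels_a), length(labels_b)
    ), call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- 0.5 * (sum_a + sum_b) - expected
  if (denom == 0) {
    return(ifelse(sum_ij == expected, 1, 0))
  }
  (sum_ij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies; in `[0, 1]`, 1 iff the partitions are identical
#' up to label renaming.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop(sprintf(
      "label vectors differ in length: %d vs %d",
      length(labels_a), length(labels_b)
    ), call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(pa)
  hb <- ent(pb)
  outer_p <- outer(pa, pb)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  denom <- (ha + hb) / 2
  if (denom == 0) {
    return(1)
  } # both partitions trivial => identical
  max(0, min(1, mi / denom))
}

#' Average accuracy rank of encoders across datasets
#'
#' Within each dataset, encoders are ranked by descending ARI (rank 1 =
#' best; ties share the mean rank); ranks are then averaged across datasets.
#' Lower is better.
#'
#' @param records Data frame with columns `dataset`, `encoder_tag`, `ari`.
#' @return List with `average_rank` (named, sorted ascending) and `ranks`
#'   (per-dataset rank matrix, datasets x encoders).
#' @export
average_rank <- function(records) {
  records <- as.data.frame(records)
  datasets <- unique(records$dataset)
  encoders <- unique(records$encoder_tag)
  ranks <- matrix(NA_real_, length(datasets), length(encoders),
    dimnames = list(datasets, encoders)
  )
  for (d in datasets) {
    sub <- records[records$dataset == d, ]
    missing <- setdiff(encoders, sub$encoder_tag)
    if (length(missing) > 0) {
      stop(sprintf(
        "encoder '%s' missing from dataset '%s'",
        missing[1], d
      ), call. = FALSE)
    }
    agg <- tapply(sub$ari, sub$encoder_tag, max) # best run per encoder
    r <- rank(-agg, ties.method = "average")
    ranks[d, names(r)] <- r
  }
  avg <- colMeans(ranks)
  list(average_rank = sort(avg), ranks = ranks)
}

#' Accuracy/efficiency trade-off set
#'
#' Per module, intersects the `top_n` encoders by ARI (descending) with the
#' `top_n` by training wall time (ascending).
#'
#' @param records Data frame with columns `module_tag`, `encoder_tag`,
#'   `ari`, `wall_time_s`.
#' @param top_n Size of each top list (default 10).
#' @return Named list (one character vector of encoders per module).
#' @export
tradeoff_select <- function(records, top_n = 10) {
  records <- as.data.frame(records)
  out <- list()
  for (m in unique(records$module_tag)) {
    sub <- records[records$module_tag == m, ]
    acc <- sub$encoder_tag[order(-sub$ari, seq_len(nrow(sub)))]
    fast <- sub$encoder_tag[order(sub$wall_time_s, seq_len(nrow(sub)))]
    out[[m]] <- intersect(
      utils::head(unique(acc), top_n),
      utils::head(unique(fast), top_n)
    )
  }
  out
}

#' Benchmark module x encoder combinations on one dataset
#'
#' For every module in `modules` and every encoder spec in `specs`, runs
#' preprocessing, graph construction, unsupervised training, clustering, and
#' (when ground-truth labels exist) ARI/NMI scoring. Wall time is measured
#' around training only. A failing combination is recorded with
#' `status = "failed"` instead of aborting the sweep.
#'
#' @param ds A [spatial_dataset()].
#' @param modules Character vector from `c("dgi", "vgae")`.
#' @param specs List of [encoder_spec()]s (or family names, expanded with
#'   defaults once the feature dimension is known).
#' @param cfg List: training config (`epochs`, `lr`, `seed`), preprocessing
#'   (`n_hvg`, `standardize`), graph (`graph_mode`, `k`, `radius`),
#'   clustering (`cluster_method`, `n_clusters` - defaults to the number of
#'   labelled domains).
#' @return Data frame of benchmark records, one row per combination.
#' @export
run_benchmark <- function(ds, modules = c("dgi", "vgae"), specs = NULL,
                          cfg = list()) {
  cfg <- utils::modifyList(
    list(
      epochs = 100L, lr = 1e-2, seed = 0L, n_hvg = 3000L,
      standardize = TRUE, graph_mode = "knn", k = 6L, radius = NULL,
      cluster_method = "gmm", n_clusters = NULL, pca_dim = 20,
      hidden_dim = 64L, out_dim = 16L
    ),
    cfg
  )
  fm <- preprocess(ds, n_hvg = cfg$n_hvg, standardize = cfg$standardize)
  g <- build_graph(ds$coordinates,
    mode = cfg$graph_mode, k = cfg$k,
    radius = cfg$radius, self_loops = TRUE
  )
  p <- ncol(fm$X)
  if (is.null(specs)) specs <- encoder_families()
  specs <- lapply(specs, function(s) {
    if (inherits(s, "encoder_spec")) s else {
      encoder_spec(s,
        in_dim = p, hidden_dim = cfg$hidden_dim,
        out_dim = cfg$out_dim
      )
    }
  })
  k_clusters <- cfg$n_clusters
  if (is.null(k_clusters) && !is.null(ds$labels)) {
    k_clusters <- length(unique(ds$labels[!is.na(ds$labels)]))
  }
  rows <- list()
  for (m in modules) {
    for (sp in specs) {
      rec <- list(
        module_tag = m, encoder_tag = sp$family, ari = NA_real_,
        nmi = NA_real_, wall_time_s = NA_real_,
        n_clusters_found = NA_integer_, seed = cfg$seed, status = "ok"
      )
      res <- tryCatch(
        {
          tcfg <- list(epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed)
          t0 <- proc.time()[["elapsed"]]
          fit <- if (m == "dgi") {
            train_dgi(fm, g, sp, tcfg)
          } else if (m == "vgae") {
            train_vgae(fm, g, sp, tcfg)
          } else {
            stop(sprintf("unknown module '%s'", m))
          }
          rec$wall_time_s <- proc.time()[["elapsed"]] - t0
          if (!is.null(k_clusters)) {
            labels_hat <- cluster_embeddings(fit$embedding,
              k = k_clusters,
              method = cfg$cluster_method,
              seed = stage_seed(cfg$seed, "cluster"),
              pca_dim = cfg$pca_dim
            )
            rec$n_clusters_found <- length(unique(labels_hat))
            if (!is.null(ds$labels)) {
              keep <- !is.na(ds$labels) # score annotated spots only
              rec$ari <- ari(ds$labels[keep], labels_hat[keep])
              rec$nmi <- nmi(ds$labels[keep], labels_hat[keep])
            }
          }
          rec
        },
        error = function(e) {
          rec$status <- "failed"
          rec$error <- conditionMessage(e)
          rec
        }
      )
      res$error <- if (is.null(res$error)) "" else res$error
      rows[[length(rows) + 1L]] <- as.data.frame(res, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
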