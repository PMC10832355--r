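# End-to-end workflows: resolve a run configuration (YAML file, defaults,
# overrides), execute a single module x encoder run or a full benchmark
# sweep, and write all artifacts (embeddings, labels, metrics, logs,
# resolved config) into an output directory. The command-line entry point in
# inst/cli/spadom.R is a thin wrapper over these functions.

default_run_config <- function() {
  list(
    dataset = NULL, # path to a dataset directory/file
    format = "csv",
    preset = NULL, # synthetic preset name, alternative to dataset
    scale = 0.25,
    module = "dgi",
    modules = c("dgi", "vgae"),
    encoder = "gcn",
    encoders = c("gcn", "sgc", "tag", "chebyshev", "sage", "gatv2"),
    hidden_dim = 64L, out_dim = 16L, hops = 2L, heads = 1L,
    graph_mode = "knn", k = 6L, radius = NULL,
    n_hvg = 3000L, standardize = TRUE,
    epochs = 100L, lr = 1e-3, seed = 0L, share_heads = TRUE,
    cluster_method = "gmm", n_clusters = NULL,
    plots = FALSE,
    out_dir = "spadom_out"
  )
}

#' Resolve a run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config file,
#' and explicit overrides. Unknown keys are a usage error.
#'
#' @param config_file Optional YAML file path.
#' @param overrides Named list of overrides (highest precedence).
#' @return A validated `run_config` list.
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop(sprintf("config file '%s' not found", config_file), call. = FALSE)
    }
    fromfile <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf(
        "unknown config key(s): %s",
        paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, fromfile)
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown config key(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (is.null(cfg$dataset) && is.null(cfg$preset)) {
    stop("config must set either 'dataset' or 'preset'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

write_resolved_config <- function(cfg, out_dir) {
  plain <- unclass(cfg)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  yaml::write_yaml(plain, file.path(out_dir, "config.yaml"))
}

load_config_dataset <- function(cfg) {
  if (!is.null(cfg$dataset)) {
    if (!file.exists(cfg$dataset) && !dir.exists(cfg$dataset)) {
      stop(sprintf("dataset path '%s' not found", cfg$dataset), call. = FALSE)
    }
    read_dataset(cfg$dataset, format = cfg$format)
  } else {
    generate_spatial_data(
      synthetic_preset(cfg$preset, scale = cfg$scale, seed = cfg$seed)
    )
  }
}

#' Generate and write a synthetic dataset
#'
#' @param cfg A `run_config` (uses `preset`, `scale`, `seed`, `out_dir`,
#'   `format`).
#' @return Invisibly, the dataset.
#' @export
cmd_simulate <- function(cfg) {
  ds <- generate_spatial_data(
    synthetic_preset(cfg$preset %||% "dlpfc-like",
      scale = cfg$scale,
      seed = cfg$seed
    )
  )
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(ds, cfg$out_dir,
    format = if (cfg$format == "h5ad") "csv" else cfg$format
  )
  write_resolved_config(cfg, cfg$out_dir)
  invisible(ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one module x encoder combination end to end
#'
#' Loads or simulates the dataset, preprocesses, builds the spatial graph,
#' trains the requested module, clusters the embedding, and writes four
#' artifacts into `out_dir`: `embeddings.tsv`, `domains.tsv`,
#' `metrics.json`, `train_log.json`, plus the resolved `config.yaml`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the embedding, labels, and metrics.
#' @export
cmd_run <- function(cfg) {
  ds <- load_config_dataset(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fm <- preprocess(ds, n_hvg = cfg$n_hvg, standardize = cfg$standardize)
  g <- build_graph(ds$coordinates,
    mode = cfg$graph_mode, k = cfg$k,
    radius = cfg$radius, self_loops = TRUE
  )
  spec <- encoder_spec(cfg$encoder,
    in_dim = ncol(fm$X),
    hidden_dim = cfg$hidden_dim, out_dim = cfg$out_dim,
    hops_K = cfg$hops, heads = cfg$heads,
    activation = if (cfg$module == "dgi") "prelu" else "relu"
  )
  tcfg <- list(
    epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed,
    share_heads = cfg$share_heads
  )
  t0 <- proc.time()[["elapsed"]]
  fit <- if (cfg$module == "dgi") {
    train_dgi(fm, g, spec, tcfg)
  } else {
    train_vgae(fm, g, spec, tcfg)
  }
  wall <- proc.time()[["elapsed"]] - t0
  k_clusters <- cfg$n_clusters %||%
    (if (!is.null(ds$labels)) length(unique(ds$labels)) else NULL)
  labels_hat <- NULL
  metrics <- list(
    module = cfg$module, encoder = cfg$encoder,
    seed = cfg$seed, wall_time_s = wall
  )
  if (!is.null(k_clusters)) {
    labels_hat <- cluster_embeddings(fit$embedding,
      k = k_clusters,
      method = cfg$cluster_method,
      seed = stage_seed(cfg$seed, "cluster")
    )
    metrics$n_clusters_found <- length(unique(labels_hat))
    if (!is.null(ds$labels)) {
      metrics$ari <- ari(ds$labels, labels_hat)
      metrics$nmi <- nmi(ds$labels, labels_hat)
    }
  }
  write_embeddings(fit$embedding, file.path(cfg$out_dir, "embeddings.tsv"))
  if (!is.null(labels_hat)) {
    utils::write.table(
      data.frame(spot_id = fit$embedding$spot_ids, domain = labels_hat),
      file.path(cfg$out_dir, "domains.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA
  )
  tl <- fit$state$train_log
  jsonlite::write_json(
    list(
      seed = cfg$seed, graph = g$params,
      encoder = unclass(spec),
      loss = if (is.data.frame(tl)) as.list(tl) else tl
    ),
    file.path(cfg$out_dir, "train_log.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_resolved_config(cfg, cfg$out_dir)
  invisible(list(
    embedding = fit$embedding, labels = labels_hat,
    metrics = metrics
  ))
}

#' Sweep modules x encoders and report the recommended combination
#'
#' Runs [run_benchmark()] over `cfg$modules` and `cfg$encoders`, then writes
#' `results.tsv` (one record per combination), `rank_table.tsv`,
#' `tradeoff.json`, and `report.json` naming the argmax-ARI combination as
#' recommended, plus the resolved config and optional PNG plots.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the benchmark record data frame.
#' @export
cmd_benchmark <- function(cfg) {
  ds <- load_config_dataset(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- run_benchmark(ds,
    modules = cfg$modules, specs = as.list(cfg$encoders),
    cfg = list(
      epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed,
      n_hvg = cfg$n_hvg, standardize = cfg$standardize,
      graph_mode = cfg$graph_mode, k = cfg$k, radius = cfg$radius,
      cluster_method = cfg$cluster_method, n_clusters = cfg$n_clusters,
      hidden_dim = cfg$hidden_dim, out_dim = cfg$out_dim
    )
  )
  utils::write.table(records, file.path(cfg$out_dir, "results.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  scored <- records[!is.na(records$ari), , drop = FALSE]
  report <- list(seed = cfg$seed, n_records = nrow(records))
  if (nrow(scored) > 0) {
    rk <- average_rank(cbind(scored, dataset = "dataset_1"))
    utils::write.table(
      data.frame(
        encoder = names(rk$average_rank),
        average_rank = as.numeric(rk$average_rank)
      ),
      file.path(cfg$out_dir, "rank_table.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    jsonlite::write_json(tradeoff_select(scored),
      file.path(cfg$out_dir, "tradeoff.json"),
      auto_unbox = FALSE
    )
    best <- scored[which.max(scored$ari), ]
    report$recommended <- list(
      module = best$module_tag, encoder = best$encoder_tag,
      ari = best$ari, nmi = best$nmi
    )
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (isTRUE(cfg$plots) && nrow(scored) > 0) {
    grDevices::png(file.path(cfg$out_dir, "ari_by_encoder.png"),
      width = 900, height = 500
    )
    graphics::boxplot(ari ~ encoder_tag, data = scored, ylab = "ARI")
    grDevices::dev.off()
    grDevices::png(file.path(cfg$out_dir, "time_by_encoder.png"),
      width = 900, height = 500
    )
    graphics::barplot(
      tapply(scored$wall_time_s, scored$encoder_tag, mean),
      ylab = "training wall time (s)"
    )
    grDevices::dev.off()
  }
  write_resolved_config(cfg, cfg$out_dir)
  invisible(records)
}
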