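# Clustering, chance-corrected scoring, ranking, and the benchmark sweep.

make_blobs <- function(n_per = 40, k = 3, d = 5, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  labels <- rep(seq_len(k), each = n_per)
  V <- centers[labels, ] + matrix(rnorm(n_per * k * d), n_per * k, d)
  list(V = V, labels = labels)
}

test_that("the mixture model recovers well-separated latent clusters exactly", {
  bl <- make_blobs()
  hat <- cluster_embeddings(bl$V, k = 3, method = "gmm", seed = 0)
  expect_equal(ari(bl$labels, hat), 1)
  expect_length(hat, nrow(bl$V))
})

test_that("clustering is deterministic given the seed and validates k", {
  bl <- make_blobs(n_per = 20, sep = 2, seed = 2)
  h1 <- cluster_embeddings(bl$V, k = 3, seed = 4)
  h2 <- cluster_embeddings(bl$V, k = 3, seed = 4)
  expect_identical(h1, h2)
  expect_error(cluster_embeddings(bl$V, k = 100), "exceeds the number of spots")
  expect_equal(cluster_embeddings(bl$V, k = 1), rep(1L, 60))
})

test_that("wide embeddings are projected onto principal components before the mixture fit", {
  bl <- make_blobs(d = 40, seed = 3)
  hat <- cluster_embeddings(bl$V, k = 3, method = "gmm", pca_dim = 10, seed = 0)
  expect_equal(ari(bl$labels, hat), 1)
})

test_that("community detection on the embedding graph separates distinct blobs", {
  bl <- make_blobs(seed = 4)
  hat <- cluster_embeddings(bl$V, method = "leiden", resolution = 1, seed = 0)
  expect_length(hat, nrow(bl$V))
  expect_gt(ari(bl$labels, hat), 0.9)
})

test_that("agreement indices are 1 for identical partitions and invariant to label renaming", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(7, 7, 5, 5, 9, 9) # same partition, renamed
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, b), 1)
  expect_equal(nmi(a, b), 1)
  expect_error(ari(a, b[-1]), "differ in length: 6 vs 5")
  expect_error(nmi(a, b[-1]), "differ in length")
})

test_that("agreement indices match independent reference implementations on random partitions", {
  set.seed(5)
  for (rep in 1:20) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
      tolerance = 1e-12
    )
  }
})

test_that("the trivial one-cluster pair scores perfect agreement, mixed trivial scores zero information", {
  one <- rep(1, 10)
  expect_equal(ari(one, one), 1)
  expect_equal(nmi(one, one), 1)
  split <- rep(1:2, 5)
  expect_equal(nmi(one, split), 0)
})

test_that("average rank orders encoders by best-run accuracy within each dataset", {
  records <- data.frame(
    dataset = rep(c("d1", "d2"), each = 3),
    encoder_tag = rep(c("gcn", "sgc", "tag"), 2),
    ari = c(0.9, 0.5, 0.7, 0.4, 0.8, 0.6)
  )
  rk <- average_rank(records)
  expect_equal(rk$average_rank[["gcn"]], 2) # ranks 1 and 3
  expect_equal(rk$average_rank[["sgc"]], 2) # ranks 3 and 1
  expect_equal(rk$average_rank[["tag"]], 2)
  # a second run of the same encoder uses its best score
  rec2 <- rbind(records, data.frame(dataset = "d2", encoder_tag = "gcn", ari = 0.95))
  rk2 <- average_rank(rec2)
  expect_equal(rk2$ranks["d2", "gcn"], 1)
  # ties share the mean rank
  tied <- data.frame(
    dataset = "d", encoder_tag = c("a", "b", "c"),
    ari = c(0.5, 0.5, 0.1)
  )
  expect_equal(unname(average_rank(tied)$ranks["d", c("a", "b")]), c(1.5, 1.5))
  expect_error(
    average_rank(records[-1, ]),
    "encoder 'gcn' missing from dataset 'd1'"
  )
})

test_that("the trade-off set intersects the most accurate with the fastest encoders per module", {
  records <- data.frame(
    module_tag = rep("dgi", 4),
    encoder_tag = c("gcn", "sgc", "tag", "gatv2"),
    ari = c(0.9, 0.8, 0.7, 0.95),
    wall_time_s = c(1, 0.5, 0.4, 30)
  )
  sel <- tradeoff_select(records, top_n = 2)
  # accuracy top-2: gatv2, gcn; speed top-2: tag, sgc -> empty intersection
  expect_identical(sel$dgi, character(0))
  sel3 <- tradeoff_select(records, top_n = 3)
  expect_setequal(sel3$dgi, c("gcn", "sgc"))
})

test_that("the benchmark sweep scores every module-encoder pair and isolates failures", {
  cfg <- synthetic_config(
    n_spots = 100, n_genes = 60, n_domains = 3,
    program_size = 20, seed = 7
  )
  ds <- generate_spatial_data(cfg)
  rec <- run_benchmark(ds,
    modules = c("dgi", "vgae"), specs = list("gcn", "sgc"),
    cfg = list(epochs = 8, seed = 1, out_dim = 8, hidden_dim = 16)
  )
  expect_equal(nrow(rec), 4)
  expect_setequal(rec$module_tag, c("dgi", "vgae"))
  expect_true(all(rec$status == "ok"))
  expect_true(all(is.finite(rec$ari)))
  expect_true(all(rec$wall_time_s > 0))
  # a broken spec is recorded, not fatal
  bad <- encoder_spec("gcn", in_dim = 5, out_dim = 4)
  rec2 <- run_benchmark(ds,
    modules = "dgi", specs = list(bad, "sgc"),
    cfg = list(epochs = 3, seed = 1, out_dim = 8, hidden_dim = 16)
  )
  expect_equal(rec2$status, c("failed", "ok"))
  expect_match(rec2$error[1], "in_dim")
  expect_true(is.na(rec2$ari[1]))
})

test_that("benchmark scoring uses annotated spots only", {
  cfg <- synthetic_config(
    n_spots = 90, n_genes = 60, n_domains = 3,
    program_size = 20, seed = 8
  )
  ds <- generate_spatial_data(cfg)
  ds$labels[1:10] <- NA # partially annotated tissue
  rec <- run_benchmark(ds,
    modules = "dgi", specs = list("gcn"),
    cfg = list(epochs = 5, seed = 1, out_dim = 6, hidden_dim = 8)
  )
  expect_true(is.finite(rec$ari))
  expect_equal(rec$status, "ok")
})
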