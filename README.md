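# spadom

Spatial domain identification for spatial omics data with interchangeable
graph deep learning modules.

Spatial transcriptomics and proteomics platforms measure an expression
vector at each *spot* (a cell, pixel, or sequencing spot) together with its
2-D tissue coordinate. spadom identifies *spatial domains* — contiguous
tissue regions with coherent expression, such as cortical layers — by
building a spot–spot proximity graph, learning per-spot embeddings with an
unsupervised graph deep learning module, and clustering the embeddings.

Because no single architecture wins on every platform, the package is a
small framework rather than one model:

- **Two training modules** — deep graph infomax (contrastive: discriminate
  true feature/topology pairs from corrupted ones) and the variational
  graph autoencoder (reconstruct the adjacency through an inner-product
  decoder, with shared-weight posterior heads by default).
- **Six encoder families** — `gcn`, `sgc`, `tag`, `chebyshev`, `sage`,
  `gatv2` — each implemented directly from its message-passing formula.
- **A benchmark harness** — sweeps module × encoder combinations on a
  labelled dataset, scores them by adjusted Rand index (ARI) and normalized
  mutual information (NMI), ranks encoders across datasets by average
  accuracy rank, intersects the most accurate with the fastest
  (`tradeoff_select()`), and recommends a combination.

Supporting parts: k-nearest-neighbor/radius spatial graphs with symmetric
normalization, HVG preprocessing, Gaussian-mixture and Leiden clustering,
readers/writers for CSV, MatrixMarket (10X layout), and AnnData `.h5ad`
(via the `python` interpreter's `anndata`), and a seeded synthetic-tissue
generator (layered and blob geometries) so the whole pipeline runs without
downloads. Training uses an in-package reverse-mode automatic
differentiation engine validated by finite-difference checks — no deep
learning runtime is required.

See `vignettes/methods.Rmd` for the model details, parameter defaults, and
the generator's scope and limitations.

## Worked example

Simulate a layered five-domain tissue (800 spots, 200 genes, log-scale
signal 3), train deep graph infomax with a GraphSAGE encoder, cluster, and
score:

```r
library(spadom)

cfg <- synthetic_config(n_spots = 800, n_genes = 200, n_domains = 5,
                        program_size = 40, signal_strength = 3, seed = 1)
ds  <- generate_spatial_data(cfg)
ds
#> <spatial_dataset> 800 spots x 200 features, 5 labelled domains

fm <- preprocess(ds)                                # lognorm + HVG + z-score
g  <- build_graph(ds$coordinates, mode = "knn", k = 6)
g
#> <spatial_graph> 800 spots, 3069 undirected edges (knn mode, self loops)

spec <- encoder_spec("sage", in_dim = ncol(fm$X),
                     hidden_dim = 64, out_dim = 16)
fit  <- train_dgi(fm, g, spec, cfg = list(epochs = 100, lr = 1e-2, seed = 1))
round(fit$state$train_log[c(1, 100)], 4)
#> [1] 3.1714 0.0002                                 # loss: epoch 1 vs 100

domains <- cluster_embeddings(fit$embedding, k = 5, method = "gmm", seed = 1)
c(ari = ari(ds$labels, domains), nmi = nmi(ds$labels, domains))
#>   ari   nmi
#> 0.988 0.984
```

The run takes about 8 seconds on one CPU. Swapping the module or encoder is
one argument (`train_vgae(...)`, `encoder_spec("chebyshev", ...)`).

To sweep all combinations and get a recommendation:

```r
records <- run_benchmark(ds, modules = c("dgi", "vgae"))   # 2 x 6 records
records[which.max(records$ari), c("module_tag", "encoder_tag", "ari", "nmi")]
```

## Command line

`inst/cli/spadom.R` wraps the same workflows:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "spadom.R", package = "spadom"))')" \
  run --preset dlpfc-like --scale 0.25 --module dgi --encoder sage \
  --epochs 100 --lr 0.01 --seed 1 --out results/run1
```

Subcommands: `simulate` (write a synthetic dataset), `run` (one module ×
encoder end to end; writes `embeddings.tsv`, `domains.tsv`, `metrics.json`,
`train_log.json`, `config.yaml`), `benchmark` (full sweep; writes
`results.tsv`, `rank_table.tsv`, `tradeoff.json`, `report.json`). A YAML
config file can replace or seed the flags (`--config`).

## Tests

```r
testthat::test_dir("tests/testthat", package = "spadom",
                   load_package = "installed")
```

The suite checks every encoder family against per-node brute-force
aggregation oracles, the autodiff engine against central finite
differences, ARI/NMI against exhaustive pair-counting/entropy oracles over
all set partitions of up to six elements (and against `mclust`/`igraph`
implementations), loss closed forms (uninformative infomax score
`2·log 2`; unit-Gaussian divergence `0.5` per latent unit), file-format
round trips, and end-to-end domain recovery on the synthetic tissue.

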