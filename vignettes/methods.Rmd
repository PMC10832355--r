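---
title: "Methods: spatial domain identification with interchangeable graph deep learning modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial domain identification with interchangeable graph deep learning modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and model

Spatial omics platforms measure an expression vector (genes or proteins) at
each *spot* — a cell, pixel, or sequencing spot — together with its 2-D
tissue coordinate. A *spatial domain* is a contiguous region with coherent
expression, such as a cortical layer. spadom identifies domains without
supervision by (1) building a spot–spot proximity graph, (2) learning a
per-spot latent embedding with a graph deep learning module whose graph
convolution smooths expression over neighborhoods, and (3) clustering the
embedding. Because no single module or graph neural network architecture
dominates across platforms, the package is organized as a small framework:
two training objectives crossed with six encoder families, plus a benchmark
harness that scores every combination on a labelled dataset and recommends
one.

## Spatial graph

`build_graph()` connects each spot to its `k` nearest Euclidean neighbors
(default `k = 6`, matching hexagonal spot grids) or to all spots within a
radius. The k-nearest-neighbor relation is symmetrized by *union*: an
undirected edge is kept when either endpoint selected the other, so no spot
is isolated by one-sided selection. Exact distance ties are broken by
ascending spot index, which makes construction deterministic. Self loops
are added by default, and the convolutional operator is the symmetric
normalization `Ã = D^(-1/2) A D^(-1/2)`; zero-degree spots map to zero rows
rather than dividing by zero. Distances are computed blockwise so memory
stays linear in the number of spots times the block size.

## Preprocessing

`preprocess()` library-size-normalizes each spot to the median total count,
applies `log(1 + x)`, ranks features by normalized dispersion
(variance/mean of the log-normalized values) keeping the top `n_hvg`
(default 3000), and z-scores each kept feature (constant features are left
at zero; their standard deviation is guarded at 1). Panels with at most 50
features — typical of protein imaging — skip the variable-feature screen
entirely, since every target in a curated panel is informative.

## Encoder registry

Each family is implemented directly from its message-passing formula over
`Ã` (or over the raw neighbor sets for the aggregation-style families), as
a plain matrix computation:

- **gcn** — stacked `H ← act(Ã H W)`; the final layer is linear.
- **sgc** — `Ã^K X W`, a single linear map after `K` propagations (no
  intermediate nonlinearity; always one layer by definition).
- **tag** — `Σ_{k=0..K} Ã^k X W_k`, one weight per hop.
- **chebyshev** — Chebyshev basis on the scaled Laplacian with
  `λ_max` fixed at 2 (the normalized-Laplacian upper bound), so
  `L̂ = -Ã`; `T_0 = X`, `T_1 = L̂X`, `T_k = 2L̂T_{k-1} - T_{k-2}`.
- **sage** — `act(W_self x_i + W_neigh · mean_{j∈N(i)} x_j)` with mean
  aggregation over structural (non-self) neighbors.
- **gatv2** — per directed edge `j→i` over `N(i) ∪ {i}`,
  `e_ij = aᵀ LeakyReLU(W_l x_j + W_r x_i)` with slope 0.2, attention by
  per-target softmax, messages `W_l x_j`; hidden heads are concatenated and
  the output layer uses a single head.

Default depth is one hidden layer (width 64) with a linear output layer;
hidden activations are PReLU (one learnable slope, initialized at 0.25) in
the infomax module and ReLU inside the autoencoder. Parameters use seeded
Glorot-uniform initialization, so a (spec, seed) pair is bit-reproducible.
Training runs on an in-package reverse-mode automatic differentiation tape;
the exported matrix forwards are the reference surface that the tests check
against per-node brute-force oracles and against the tape path.

## Module 1: deep graph infomax

Negative samples are built by the corruption function: a seeded random
permutation of the feature rows with the topology left unchanged. The
readout is the component-wise logistic of the embedding column means; a
bilinear discriminator `logistic(hᵀ W S)` scores local–global pairs. The
loss is the binary cross-entropy with true spots labelled 1 and corrupted
spots 0; it equals `2·log 2` when the discriminator is uninformative, which
gives a natural training-progress reference. A fresh corruption is drawn
every epoch (the harder, resampled variant; disable with
`resample_corruption = FALSE`). The final embedding is the deterministic
positive-branch encoder output at the trained parameters.

## Module 2: variational graph autoencoder

The first layer is the chosen family's single rectified convolution; the
posterior heads are `μ = Ã X̃ W1` and `log σ²`, which **share `W1` by
default** (`share_heads = TRUE`), making `μ` and `log σ²` element-wise
identical — a structural property the tests assert directly. The
conventional variant with a separate log-variance head is available via
`share_heads = FALSE`. A latent sample `Z = μ + σ ⊙ ε` feeds the
inner-product decoder `logistic(ZZᵀ)`. The loss is the class-weighted
reconstruction cross-entropy (positive-class weight
`(n² − nnz)/nnz` balancing the sparse edge class; self loops count as
positives) plus `kl_scale` times the Gaussian divergence from the
standard-normal prior. The divergence is summed over latent units and
averaged over spots, and `kl_scale` defaults to `1/n` — i.e. the divergence
enters at order `1/n²` relative to its raw sum, a deliberately weak prior
that keeps reconstruction dominant at these problem sizes; pass
`kl_scale = 1` for the conventional weighting. The embedding is the
posterior mean `μ`, deterministic at inference.

## Clustering and evaluation

`cluster_embeddings()` fits a Gaussian mixture with `k` components
(full-covariance first, falling back to more constrained covariance models
and finally k-means if the fit is degenerate), after projecting embeddings
wider than 20 columns onto their leading principal components; or runs
Leiden community detection on a k-nearest-neighbor graph of the embedding.
Agreement with ground truth uses the in-package adjusted Rand index and
normalized mutual information (arithmetic-mean normalization), both
validated against exhaustive pair-counting/entropy oracles and against
independent implementations in `mclust` and `igraph`. When a dataset is
partially annotated, only labelled spots are scored. `average_rank()`
summarizes encoder accuracy across datasets by mean rank (best run per
encoder within a dataset); `tradeoff_select()` intersects the most accurate
with the fastest encoders per module; `run_benchmark()` sweeps modules ×
encoders, recording failures per combination (`status = "failed"`) instead
of aborting, and measuring wall time around training only.

The benchmark harness defaults to 100 epochs at learning rate `1e-2` with a
64-dimensional hidden layer and 16-dimensional embedding. These are the
package's desk-scale defaults, chosen for ~1000-spot problems on one CPU;
single-run training (`train_dgi()`/`train_vgae()`) defaults to the more
conservative 500 epochs at `1e-3`.

## Synthetic generator: scope and limitations

`generate_spatial_data()` provides two geometries. `layers` places spots on
a jittered square grid in the unit square and assigns domains as contiguous
horizontal bands of nearly equal occupancy (a cortical-laminae analogue);
`blobs` scatters spots around uniformly drawn centers and labels each spot
by its nearest center (an imaging-data analogue). Expression is lognormal:
per-gene baseline `N(0, 0.5)` on the log scale, plus the domain's program
shift (`signal_strength × noise_sd`; programs are disjoint gene blocks),
plus `N(0, noise_sd)` log noise, exponentiated, then multiplicative
Bernoulli dropout. `expected_separability()` gives the monotone difficulty
score `signal / sqrt(1 + dropout/(1 - dropout))`. Presets mirror common
platform shapes (3600 × 3000 layered; 13800 × 347 and 16700 × 43 blobs)
with a `scale` knob for desk-scale runs.

The generator is deliberately simple: domains are geometrically convex or
banded, programs are disjoint, noise is homoscedastic and spatially
uncorrelated, and there are no batch effects, spatial expression gradients
within domains, or cell-type mixtures at spot resolution. Accuracy numbers
obtained on it are upper bounds on what the same pipeline achieves on real
tissue, and are meant for comparing combinations under identical
conditions, not for forecasting absolute performance on any platform.

## Numerical choices

- All training is float64 (R numerics); no stochastic minibatching — every
  epoch is a full-graph pass, so runs are bit-reproducible given the seed.
- One user seed is fanned out into independent stage seeds (encoder
  initialization, discriminator/heads, corruption, reparameterization
  noise, clustering) by a fixed integer hash, so changing one stage does
  not silently shift another's stream.
- Adam with bias correction (`β₁ = 0.9`, `β₂ = 0.999`, `ε = 1e-8`).
- Cross-entropies are computed from logits with the softplus
  stabilization; probability-space helpers clamp at `1e-12`.
- Gradient correctness of the tape engine is enforced by central
  finite-difference checks through the exact training computations of both
  modules and all six families.

## Limitations

Training is dense-matrix full-batch: memory for the autoencoder decoder is
`O(n²)`, which caps practical problem sizes at a few thousand spots in this
implementation. The mixture-model clustering assumes the number of domains
is known (or taken from annotations); Leiden mode does not. Histology
images, 3-D coordinates, and multi-sample integration are out of scope.
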