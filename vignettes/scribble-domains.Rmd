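---
title: "Scribble-guided spatial domain identification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scribble-guided spatial domain identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scribseg)
```

## The model

A tissue slice measured on a spot array yields counts `X ∈ N^{n×g}` and
array coordinates. After log-normalisation, selection of `h` highly
variable genes and projection to `p` principal components, each spot is a
point `y_i ∈ R^p` sitting on a lattice. The segmentation model is a small
convolutional network applied to the `H×W×p` rasterisation of these
vectors: a 1×1 convolution (p→p), two Inception blocks, a 1×1 convolution
to `s` channels, with ReLU and batch normalisation between stages. Each
Inception block runs four parallel paths — 1×1, 3×3 and 5×5 convolutions
and a 3×3 max-pool followed by a 1×1 convolution — and concatenates them:
256 features (160 + 64 + 16 + 16) in the first block, 128 (96 + 16 + 8 +
8) in the second. The multi-scale paths matter because spatial domains are
defined jointly by a spot's own expression (1×1) and its neighbourhood
context (3×3, 5×5, pooling).

A channel-wise softmax of the final batch-normalised activations gives the
response map `r_i ∈ R^s`, a proper probability vector per spot; the
predicted label is `c_i = argmax_k r_{i,k}` (ties broken toward the lowest
channel, which makes runs reproducible). The softmax is required by the
loss: both terms are cross-entropies of the form `−ln r_{i,·}` and demand
`r ∈ (0, 1]`; batch-normalised activations alone can be negative.

Training minimises

`α · L_sim + (1−α) · L_scr`,

where `L_sim = Σ_i −(1−u_i) ln r_{i,c_i}` self-trains unscribbled spots on
their own argmax and `L_scr = Σ_i −u_i ln r_{i,w_i}` pins scribbled spots
to their scribble label `w_i`. The self-training targets are recomputed
from the current response every iteration and treated as constants in the
gradient, as in the unsupervised-segmentation CNNs this architecture
descends from. At `α = 1` (or with no scribbles at all) the model runs
fully unsupervised; at `α = 0` it reduces to fitting the scribbles.

## Hexagonal-to-rectangular mapping

Visium spots sit on a hexagonal lattice in array coordinates with
`row + col` even. The shear `(i, j) = (row, (row + col)/2)` is the
unimodular map under which the six physical hex neighbours land exactly on
`(i±1, j), (i, j±1), (i−1, j−1), (i+1, j+1)`; the test suite verifies this
exhaustively on a 10×10 lattice. ST's square lattice passes through
unchanged with the 4-neighbourhood. Grid cells with no spot are zero-filled
and masked: they pad convolution receptive fields but are excluded from
the loss, and the network input is multiplied by the mask, so values
stored in background cells can never influence training (asserted by a
perturbation test).

## Automatic scribbles

When no expert annotation exists, an mclust Gaussian-mixture clustering of
the PC vectors (`G = s`, non-spatial) provides initial labels. Because a
non-spatial clustering is noisy precisely at domain boundaries, only spots
whose label agrees with *all* of their neighbours are kept as scribbles;
the rest are cleared. Boundary spots with incomplete neighbourhoods are
judged on their existing neighbours — the alternative (disqualifying them)
discards real consensus signal at the tissue edge, and is available via
`strict = TRUE`. During training each surviving scribble is then dropped
independently with probability β per iteration (i.i.d. Bernoulli — the
natural reading of per-iteration random removal), which lets the network
overrule the occasional wrong scribble that survives the consensus filter.
Dropout defaults to 0 in expert-scribble mode: expert strokes are treated
as trustworthy.

## Label-free model selection

For each candidate `(α, β)` the trained labelling `C` is scored by
`log v = log p(y|C) + log p(C) + log q`:

* `p(y|C)`: each cluster is modelled as a Gaussian with the empirical mean
  and covariance of its member PCs; evaluated via Cholesky in the log
  domain.
* `p(C)`: the Potts prior
  `p(C_i) = exp((2γ/|N(i)|) Σ_{j∈N(i)} δ(C_i, C_j)) / Z_i`, with `Z_i`
  summing the numerator over the `s` candidate labels of spot `i`. We use
  the customary couplings γ = 3 (Visium) and γ = 2 (ST). Spots with no
  neighbours get the uniform `1/s` — the `2γ/|N(i)|` factor is undefined
  at `|N(i)| = 0`.
* `q = exp(−λ Σ_j tr(Σ_j))`, λ = 100: a within-cluster variance penalty
  that favours tight clusters.

The grid search covers α ∈ {0.05, 0.10, …, 0.95} (19 values) and, in auto
mode, β ∈ {0.25, 0.30, 0.35, 0.40} (76 combinations), each run seeded by a
deterministic hash of the master seed and the grid coordinates so the
whole search replays exactly.

## Numerical and design choices

* **Covariance convention.** Cluster covariances use the `n−1` (sample)
  denominator, matching R's `cov()`. A `cov_method = "population"` switch
  exists. Covariances are ridge-regularised (`+1e−6·I`) for the likelihood
  only — tiny clusters otherwise make `p(y|C)` undefined — while the
  variance penalty uses the unridged trace so a zero-variance clustering
  scores exactly `log q = 0`.
* **Log-domain scoring.** `v` itself underflows for n in the hundreds;
  all comparisons use `log v`, which is exact and monotone.
* **Loss scale vs. step size.** The reported losses are the printed sums
  over spots. The gradient step divides by the number of occupied spots
  (equivalently, optimises the per-spot mean), so the default learning
  rate (0.1, momentum 0.9, full-grid batch, 300 iterations) is stable
  regardless of lattice size. This is a reparametrisation of the learning
  rate only; α's balance between the two terms is untouched.
* **Normalisation.** Counts are scaled to the median library size before
  `log1p` — the standard dependency-free equivalent of the usual
  preprocessing in this field; spots with proportional count vectors
  normalise identically. HVGs are ranked by plain variance of the
  normalised values with lexicographic tie-breaks (deterministic; a
  mean–variance-trend criterion could be substituted behind the same
  interface). PCs enter the network unstandardised by default — their
  relative scale carries the variance ordering — with standardisation
  available upstream if wanted.
* **Total-loss prefactor.** The two-term objective is implemented as the
  plain convex combination; a spurious extra summation over clusters on
  the scribble term would only rescale the effective α grid, not change
  the family of optima.
* **Optimiser and initialisation.** No optimiser is canonical for this
  family; SGD with momentum and fan-in uniform initialisation follow the
  unsupervised-segmentation lineage. Every random draw (initialisation,
  dropout, mclust) flows from explicit seeds; two runs with the same seed
  are bit-identical, which the tests assert.
* **Stopping.** A fixed iteration budget (default 300) rather than a
  label-count collapse criterion: it is deterministic, trivially
  comparable across grid points, and the loss traces show the runs
  plateau well before it on the problem sizes used here.

## What the synthetic generator does and does not emulate

`make_lattice_dataset()` plants `s` contiguous domains (banded strips,
emulating layered cortex; or discs in background, emulating tumour foci)
on an ST or Visium lattice, draws domain means with nearest-pair distance
Δ, and adds isotropic Gaussian noise σ per PC dimension, so Δ/σ is the
single separability knob. The default test conditions use a 24×24 lattice,
s = 3 bands, Δ/σ = 4, 30% stroke-like scribble coverage generated by
random walks inside each domain, and 10% label corruption when a noisy
initial clustering is needed. A log-linear Poisson count mode exercises
the full preprocessing path.

Real tissue differs in ways the generator deliberately ignores:
non-Gaussian and spot-to-spot correlated noise, domain-specific library
sizes, irregular tissue boundaries and holes, mixed-composition spots at
domain borders, and annotation error in the "truth". Passing the recovery
tests therefore demonstrates that the estimator is implemented correctly
and can recover planted structure at realistic separations — not that it
attains any particular accuracy on real tissue.

Problem sizes throughout the tests (24×24 lattices, 300 iterations, 5-PC
inputs, 5-iteration grid-search smoke runs) are chosen to exercise every
code path at desk scale while keeping the full suite fast; the method
itself has no dependence on these sizes.

## Known limitations

* Batch statistics are computed over the whole grid including background
  cells; with very sparse tissue masks this shifts the normalisation
  statistics (labels remain unaffected by background *values*, which are
  masked to zero).
* mclust occasionally degenerates on pathological inputs (e.g. identical
  points); the fallback assigns a single cluster, and the consensus filter
  then produces uniform scribbles.
* The goodness score compares labellings for a *fixed* s; choosing s is
  out of scope.
* Training is CPU-bound full-batch gradient descent; very large slides
  (tens of thousands of spots) will be slow, and minibatching or GPU
  support is not implemented.
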