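---
title: "Estimating structure-level brain age from surface meshes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating structure-level brain age from surface meshes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucage)
```

## The problem

Brain age estimators regress chronological age on imaging features; the
gap between predicted and actual age indexes deviation from normative
aging and rises in mild cognitive impairment (MCI) and Alzheimer's
disease dementia (ADD). Most estimators operate on the whole brain at
once. `strucage` instead estimates an age per *structure* — the cortex
and seven subcortical structures (accumbens, amygdala, caudate,
hippocampus, pallidum, putamen, thalamus) per hemisphere — from
template-registered triangulated surface meshes, so that each
structure's aging trajectory can be analyzed separately and jointly.

The pipeline has five stages:

1. **Meshes to graphs.** Each structure's template triangulation defines
   one fixed graph: nodes are vertices, edges are triangle edges. Node
   features are the scan's vertex coordinates (mm) in template
   correspondence, centered per scan and divided by 100. Cortical nodes
   carry 6 features (inner and outer surface coordinates), subcortical
   nodes 3. Structure combinations ("all", "cortex", "subcortical", or a
   single structure) are disjoint unions of the per-hemisphere graphs
   with features zero-padded to a common width.
2. **Coarsening.** A multiscale binary partition pairs every node with a
   graph neighbor at each scale, so stride-2 1D pooling is a valid graph
   pooling and node counts halve exactly (template counts are powers of
   two).
3. **Network.** A residual Chebyshev graph-convolutional network maps the
   feature matrix to a single age, with a learnable soft-bin head.
4. **Inference and bias correction.** Predictions are averaged over an
   ensemble of seeds and over randomly rotated copies of the scan
   (test-time augmentation, TTA); the age-dependent residual bias is
   estimated on validation data by LOWESS, parametrized by a smoothing
   spline, and subtracted.
5. **Statistics.** Cross-sectional OLS quantifies how much older each
   structure "looks" in MCI and ADD at a fixed chronological age;
   a longitudinal mixed model on initially-healthy subjects with repeated
   scans quantifies each conversion group's *aging pace*.

## Spectral convolution and its domain

For a structure graph with adjacency $A$ and degree matrix $D$, the
symmetric-normalized Laplacian is $L = I - D^{-1/2} A D^{-1/2}$
(rows of isolated nodes are zeroed). Its spectrum lies in $[0, 2]$, and
the rescaled operator $\tilde L = (2/\lambda_{\max}) L - I$ has spectrum
in $[-1, 1]$, the natural domain of Chebyshev polynomials. A filter of
order $K$ computes

$$ Y = \sum_{k=0}^{K-1} T_k(\tilde L)\, X\, \theta_k + b, \qquad
   T_0 = I,\; T_1 = \tilde L,\; T_k = 2 \tilde L T_{k-1} - T_{k-2}, $$

evaluated by the three-term recursion applied to $X$ (dense powers of
$\tilde L$ are never formed). $K$ sets the filter's spatial support: the
output at a node depends on its $(K-1)$-hop neighborhood. The backward
pass reuses the same structure: because $\tilde L$ is symmetric, the
input gradient is $\sum_k T_k(\tilde L)\, (\nabla Y)\, \theta_k^\top$,
evaluated with a Clenshaw recurrence in $K$ sparse products.

**Why the Laplacian is symmetric-normalized with binary weights.** The
mesh source does not dictate a weighting; binary weights keep the
operator purely combinatorial, identical for every scan of a structure,
and reproducible. Inverse-edge-length weights are available
(`mesh_to_graph(..., weighting = "invlength")`) for users who prefer
geometry-aware smoothing.

**How $\lambda_{\max}$ is estimated.** Sphere-like meshes have
near-degenerate top Laplacian eigenvalues, on which plain power
iteration stalls: its Rayleigh quotient can plateau about $10^{-3}$
below $\lambda_{\max}$, which after rescaling pushes eigenvalues of
$\tilde L$ *outside* $[-1,1]$ and destabilizes the Chebyshev recursion's
guarantees. `scaled_laplacian()` therefore runs a deterministic Lanczos
iteration (at most 100 steps, full reorthogonalization) and adds the top
Ritz pair's residual bound, giving an upper bound on $\lambda_{\max}$
that is tight in practice and is capped at the theoretical bound 2.
Edgeless graphs fall back to $\lambda_{\max} = 2$, making
$\tilde L = -I$.

## Coarsening: making stride-2 pooling valid on meshes

`binary_partition()` builds, per scale, a perfect matching of the graph:
a greedy heavy-edge matching seeded by node degree (lowest-degree node
first, ties by index), repaired to perfection with augmenting paths.
Pair $i$ occupies positions $2i-1, 2i$ of the scale's ordering and
becomes coarse node $i$; coarse nodes inherit the union of their
members' edges (weights summed). On all synthetic templates every pair
is graph-adjacent and no repair fallback triggers; if a pathological
graph leaves unmatched nodes, nearest remaining nodes (BFS distance,
within their connected component) are paired and a warning counts the
non-adjacent pairs. Construction is seed-free and deterministic, so
training and prediction always share one hierarchy. Because template
counts are powers of two and matchings are perfect, no fake-node padding
is needed and counts halve exactly.

## Architecture

`build_age_network()` assembles, for `n_residual_blocks = 3` (defaults
in parentheses):

* Chebyshev convolution, order `K_first` (9), 64 filters — a large first
  receptive field — followed immediately by pooling;
* three residual blocks, each pre-activation
  BN → ReLU → conv(`K_block` = 6) → BN → ReLU → conv + identity skip,
  each followed by pooling (4 pooling events total, so the hierarchy
  needs 4 levels and node counts divisible by 16);
* BN → convolution with 128 filters → global average pooling over nodes;
* a dual-branch soft-bin head: dense(75) + ReLU produces 75 nonnegative
  *bin ages* (input-dependent and learnable — no fixed age grid is
  imposed), dense(75) + dropout(0.75) + Softmax produces bin
  probabilities; their elementwise product is combined by a final linear
  dense(1) into the age estimate.

Where the layer layout leaves genuine choices open we chose: kernel
orders `K_first = 9` / `K_block = 6` (configurable and logged with every
run); max pooling (mean available); dropout only on the Softmax-branch
dense layer; skip connections never cross a pooling boundary (the
addition happens before each pool). Weight initialization is
variance-scaling uniform under a per-network seed; batch size defaults
to 16 (a free choice; any small power of two behaves
similarly). The output bias can be initialized at the training-set mean
age (`output_bias_init`); with RMSprop steps of order `lr` per weight,
starting the head at the cohort mean removes the long "learn the age
scale" phase and is standard practice for regression heads.

## Training regime

MSE loss plus an L2 penalty ($\lambda = 10^{-12}$ — near-vanishing, kept
for parity with the full-scale regime), RMSprop (initial learning rate
0.001, $\rho = 0.9$), random rotations within ±15° per training scan and
±5° at validation/test, validation MAE monitored with TTA = 3 (the mean
of three augmented predictions per scan is scored), learning rate
divided by 10 after 15 non-improving epochs, stop after 30, best
validation weights restored.

**Batch-norm statistics at inference.** With momentum-0.99 running
averages, the statistics seen at inference lag hundreds of updates
behind the batch statistics the weights co-adapt to; on CPU-scale runs
(tens of epochs, tens of batches per epoch) this squashes
inference-mode activations badly. `train_age_network()` therefore
replaces the running statistics with exact training-set moments
(`recalibrate_bn_stats`) before every validation evaluation; the best
snapshot carries the recalibrated statistics.

**Determinism.** All randomness (shuffling, rotations, dropout,
initialization) flows through R's RNG under the configured seeds;
training curves are bit-identical across reruns on one thread, and
`run_experiment()` seeds its prediction stages so whole experiment
outputs reproduce byte-identically.

## Ensemble, TTA and bias correction

Deployment-scale inference uses 20 networks per structure configuration
(different seeds) × TTA 20, i.e. 400 raw estimates per scan, aggregated
by the mean. Brain-age regressors overestimate young and underestimate
old subjects (regression to the mean); the residual (predicted − true)
is smoothed against true age on the validation set with LOWESS (span
0.3, 2 robustness iterations) and the curve is parametrized by a cubic
smoothing spline (`spar = 0.1`) for fast evaluation, with constant
extrapolation outside the validation age range. At test time the
correction is evaluated, by default, at the *raw predicted* age — in
deployment the true age is the quantity being estimated — with
`reference_age` available to evaluate at true age for evaluation-style
residual plots. At least 30 validation pairs are required; a linear
30-point curve is already stable, and `run_experiment()` degrades to the
identity correction (with a warning) below that.

## Statistical models

**Cross-sectional** (per structure, baseline scans, OLS):
$PA_i = \beta_0 + \beta_1\,\mathrm{Age}_i + \beta_2\,\mathrm{Diagnosis}_i + \varepsilon_i$,
diagnosis treatment-coded against healthy. The MCI and ADD coefficients
are the extra predicted years carried by a diagnosis at fixed
chronological age.

**Longitudinal** (per structure, REML mixed model on subjects healthy at
baseline with ≥2 scans and age ≥70 at the last scan, grouped by last
diagnosis):
$$PA_{ij} = \beta_0 + \beta_g + \beta_1\,\mathrm{Age}_{i0}
  + \beta_{2,g}\,\Delta_{ij} + b_{0i} + b_{1i}\,\Delta_{ij}
  + \varepsilon_{ij},$$
with conversion-group main effects $\beta_g$ (non-converter reference),
one time-since-baseline slope $\beta_{2,g}$ per group (no common slope
term), and correlated per-subject random intercept and slope (falling
back to uncorrelated when the fit is singular). The reported converter
effects are the group offsets and the slope contrasts
$\beta_{2,g} - \beta_{2,\mathrm{HC}}$, with Satterthwaite degrees of
freedom. We include the group main effects because a converter *offset*
(being statically older at baseline) and a converter *pace* (aging
faster over follow-up) are distinct scientific quantities: without group
intercepts, a static offset would be absorbed into the group slopes and
the two effects could not be separated.

The **aging pace** of a converter group is reported as the signed
percent deviation of its slope from the non-converter slope,
$(\beta_{2,g}/\beta_{2,\mathrm{HC}} - 1)\times 100$, matching the
convention in which an identical pace is 0% and a slower pace is
negative; the ratio is refused when the non-converter slope is
numerically zero. P-values of all structure × contrast tests in one
analysis table are Benjamini–Hochberg FDR-corrected together, and 0.05
(FDR-corrected) is the reporting threshold.

## What the synthetic data emulates — and what it does not

`make_template()` builds watertight sphere-like triangulations with
exactly the per-structure template node counts. A subdivided octahedron
has $2^{2k+2} + 2$ vertices; exact powers of two are reached by manifold
shortest-edge collapses (2 collapses for even powers, about half the
mesh for odd powers), and radii (5–15 mm subcortical, 60 mm cortical)
keep average neighbor edge lengths under 2 mm / 3 mm respectively.
Shape varies through ≤9 smooth radial displacement fields (low-order
real spherical harmonics, unit RMS, orientation seeded).

A subject's mesh at a scan is the template plus field displacements with
coefficients affine in the *effective age*
$\mathrm{age}_0 + \mathrm{pace}\times t + \mathrm{offset}$: the default
gains are 0.05 mm/yr uniform radial growth plus 0.02 mm/yr on two
low-order asymmetries. Each subject additionally carries a random
constant shape component on all fields (SD 0.15 mm per field); its
projection onto the age-linked fields plays the role of a biological
brain-age gap of roughly ±3 years, which is what keeps synthetic test
MAE in a realistic few-year range rather than at zero. Per-scan smooth
noise (SD 0.05 mm per field) models acquisition variability. Converter
groups carry offsets (+0.93 / +2.29 years) and pace multipliers
(×1.1228 / ×1.3116) at whole-brain scale, and baseline-diagnosed groups
carry amygdala-scale offsets (+3.48 / +7.97 years), so downstream
recovery can be compared against known generating values of realistic
magnitude.

What the generator does **not** emulate: anatomically realistic cortical
folding or subcortical shape, scanner/site effects, nonlinear aging
trajectories (an optional quadratic term can be injected through the
gains to exercise the bias correction), diagnosis-dependent shape
*patterns* (pathology only shifts and accelerates the shared aging
direction), and missingness or irregular scan schedules. Passing
end-to-end tests therefore demonstrates that the machinery — graphs,
coarsening, gradients, training, correction, statistics — is correct and
identifiable under a known generative model, not that real-data accuracy
numbers transfer.

## Numerical choices and degenerate inputs

* Lanczos upper bound for $\lambda_{\max}$ (see above); tolerance
  $10^{-8}$ on spectrum containment is asserted densely in tests.
* Clenshaw recurrence for the convolution's input gradient; gradients of
  every layer are verified against central finite differences.
* Matching ties broken by node index; hierarchy construction seed-free.
* Max-pooling ties route the gradient to the first row of the pair.
* Isolated graph nodes get zero Laplacian rows; edgeless graphs use the
  $\lambda_{\max} = 2$ fallback.
* BN $\epsilon = 10^{-3}$; RMSprop $\epsilon = 10^{-7}$.
* Non-bijective orderings, mismatched shapes, subject overlap between
  train and validation (data leakage), mixed ensemble configurations,
  absent diagnosis levels, and zero non-converter slopes are all
  rejected with typed errors rather than silently repaired.

## Problem sizes used by the test suite and acceptance script

The packaged checks are sized for a single CPU: the learnability check
trains a 16-filter, 2-block network on a 250-subject single-structure
(256-node) cohort for at most 50 epochs and compares its test MAE
against predicting the training-mean age; statistical calibration uses
100 simulation replicates (1000 subjects cross-sectional, 150 × 3 scans
longitudinal) plus a 200-replicate permuted-diagnosis null; the
structural checks build all sixteen per-hemisphere templates (47,616
merged nodes) and a 17,440-subject split manifest. The full-scale
configuration (10 structure configurations × 20 seeds, 64/128 filters)
is expressed by the defaults of `experiment_config()` but is not trained
by the tests.

## Known limitations

* The network is pure R (sparse `Matrix` kernels); it is fast enough for
  the packaged problem sizes but not for 47,616-node whole-brain
  training at full filter counts on a single CPU.
* Only blossom-free augmenting paths are attempted during matching
  repair; this suffices for triangulated 2-manifolds, which is the
  intended domain.
* The longitudinal model assumes linear within-subject trajectories over
  follow-up and a common residual variance across groups.
* Bias correction at the raw predicted age (the deployment default)
  under-corrects slightly when the raw prediction is far from the true
  age; evaluation-style analyses should pass the true age explicitly.
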