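---
title: "Fuzzy recurrence plots of deep image features for two-class survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy recurrence plots of deep image features for two-class survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FRPSurv)
```

## The problem and the method

Immunohistochemistry (IHC) stains visualize a protein of interest in a
tissue section — typically as brown (DAB) deposits over a blue
(hematoxylin) background. FRPSurv addresses a small-cohort, two-class
problem: classifying IHC images of tissue dissected adjacent to a
tumor into patients who survived more versus less than five years
after surgery. Cohorts of this kind are far too small to train a deep
network from scratch, so the pipeline combines a fixed convolutional
feature extractor with a compact dynamical-systems representation and
a recurrent classifier:

1. **Deep features.** An image is resized to a backbone's canonical
   input (224×224×3 for ResNet-101 and DenseNet-201, 331×331×3 for
   NASNet-Large) and pushed through the network; the flattened
   activation of the final global-average-pooling layer is the feature
   vector `g` of length N (2048, 1920 or 4032).
2. **Compression.** Fuzzy c-means (FCM) clustering of the N scalar
   feature values, with `n = 13` clusters, replaces `g` by the short
   sequence `x` of its 13 cluster centers.
3. **Embedding.** Time-delay embedding with dimension `d` and delay
   `tau` turns `x` into `M = n - (d - 1) tau` phase-space states; the
   defaults `d = 1`, `tau = 1` give the identity embedding, `M = 13`.
4. **Fuzzy recurrence plot (FRP).** A second FCM run (`c = 3` clusters,
   exponent `m = 2`) assigns each state membership grades over the
   clusters. The state-to-state similarity matrix is the max–min
   composition of these grades, with reflexivity forcing a unit
   diagonal and symmetry guaranteed by construction. The result is an
   M×M grayscale matrix in [0, 1].
5. **Sequence classification.** The FRP is read as a time series: M
   time steps (rows), M features per step (columns). A bidirectional
   LSTM processes the sequence in both directions; the two final hidden
   states feed a fully-connected softmax head producing two class
   scores.

Baselines mirror the classical alternatives: a linear SVM on the raw
deep features, and a linear SVM on 14 Haralick statistics of
gray-level co-occurrence matrices (GLCM). A stratified k-fold
cross-validation harness reports accuracy, sensitivity, specificity,
precision and F1 from pooled out-of-fold confusion counts, with the
longer-survival class as the positive condition.

## Fuzzy c-means: the core primitive

FCM minimizes the weighted within-cluster sum of squares
$F_m = \sum_{i}\sum_{k} \mu_{ik}^m \lVert s_i - v_k \rVert^2$ subject
to $\sum_k \mu_{ik} = 1$, alternating the center update
$v_k = \sum_i \mu_{ik}^m s_i / \sum_i \mu_{ik}^m$ with the
inverse-distance-ratio membership update
$\mu_{ik} = 1 / \sum_j (\lVert s_i - v_k\rVert / \lVert s_i -
v_j\rVert)^{2/(m-1)}$ until the membership matrix changes by at most
`delta` (maximum absolute elementwise difference) or `maxIter`
iterations have run. It is implemented from scratch in the package
because the max–min FRP construction needs the raw membership matrix
and a controlled, seeded initialization.

Choices the fitting procedure makes where the standard formulation is
silent:

- **Initialization.** Membership rows are drawn from a symmetric
  Dirichlet(1, …, 1), seeded. A single seeded run is performed; there
  is no restart machinery.
- **Coincidence rule.** If a point lies within 1e-12 of one or more
  centers, its membership is split equally over the coincident centers
  and set to 0 elsewhere, so the update never divides by zero.
- **Cluster order.** After convergence, clusters are relabelled
  ascending by center value (scalar data) or by the centers' first
  principal coordinate (multivariate data, sign fixed by the
  largest-magnitude loading). Downstream sequences are therefore
  deterministic functions of the data and seed.
- **Compressed-sequence order.** The 13 compression centers are
  reported sorted ascending — a permutation-invariant, reproducible
  convention; an "assignment order" alternative (clusters by first
  appearance of their hard assignment along the feature vector) is
  available behind a flag for users who prefer a content-dependent
  ordering.
- **Exponent for the compression run.** The fuzzy exponent is `m = 2`
  for both FCM uses (compression and FRP), configurable separately if
  needed.

The degenerate cases are defined, not accidental: `c = 1` returns unit
memberships at the mean; a constant feature vector compresses to
coincident centers at its value; requesting more clusters than
distinct points is an error.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `n` | 13 | compression clusters = compressed length |
| `frpC` | 3 | FCM clusters for the FRP memberships |
| `m` | 2 | fuzzy exponent (both FCM uses) |
| `d`, `tau` | 1, 1 | embedding dimension and delay (identity) |
| `delta` | 1e-5 | FCM convergence threshold |
| `maxIter` | 100 | FCM iteration cap |
| `maxEpochs` | 300 | LSTM epoch cap |
| `batchSize` | 150 | clamped to the training-set size |
| `learningRate` | 0.01 | Adam step size |
| `gradientThreshold` | 1 | global L2-norm clipping |
| `hiddenSize` | 100 | LSTM width per direction |
| `k` | 10 | cross-validation folds |

A single pipeline seed fans out into independent stage seeds (backbone
weights, compression, FRP, training, fold assignment), so an entire
experiment is reproducible from one integer.

The LSTM's hidden size, optimizer and loss are genuinely open choices
for this architecture; the package uses hidden size 100, Adam at the
configured learning rate with gradient-norm clipping at the configured
threshold, and the two-class cross-entropy. A batch size larger than
the training set (150 versus the 72-image training folds of an
80-image cohort) simply means full-batch training. Training also stops
once the training cross-entropy falls below `lossTol = 1e-3`: at that
point every training example is classified with probability ≥ 0.999
and further epochs cannot change the fitted decision materially. No
class weighting is applied by default.

## The backbone layer: what is and is not inside

No deep-learning framework is part of the package's dependency set.
The backbone component is therefore built in-package as explicit layer
graphs — ResNet-101's 3-4-23-3 bottleneck stages and DenseNet-201's
6-12-48-32 dense blocks, executed by an im2col + BLAS forward engine —
with seeded He-normal random weights and identity-like channelwise
affines in place of trained batch-normalization statistics. The
feature *length* at the global-average-pooling layer (2048 and 1920)
is a pure property of the architecture, so every shape contract of the
pipeline holds exactly; the feature *values* under random weights are
architecture-faithful but untrained, which is sufficient for the
pipeline's plumbing and for structural evaluation, not for clinical
feature quality. NASNet-Large is registered through its cell-stacking
shape rule (6 concatenated branches × 168 base filters × two
filter-doubling reductions = 4032) without a numerical forward pass;
its cell graph is out of proportion to its role here. Externally
obtained pretrained weights can be layered onto the same graph
structures; fine-tuning is likewise a hook, not a requirement.

For the same reason the bidirectional LSTM is implemented directly,
with analytic backpropagation through time verified against numerical
differentiation, and a reference single-step cell (`lstmCellStep`)
written as literal per-gate equations pins the batched training layer
on random instances at 1e-5.

## The GLCM baseline

The texture baseline quantizes the grayscale image (ITU-R 601
luminance) to 8 levels, counts symmetric co-occurrences at distance 1
for angles 0/45/90/135, and computes the classical 14 Haralick
statistics per angle, averaged over angles. The 14th statistic (the
maximal correlation coefficient) is defined as 0 when its eigenproblem
is degenerate — fewer than two occupied gray levels, or a non-finite
second eigenvalue — so a constant image yields a defined, finite
descriptor. Natural logarithms are used throughout, with 0 log 0 = 0.

## Synthetic data: what it emulates, and what it does not

Two seeded generators make the full pipeline testable with no
downloads.

**Images.** Two-class stained-tissue-like textures: soft-edged
DAB-brown disks over a hematoxylin-blue background with additive
Gaussian noise (sd 0.02), 128×128 by default. The class signal is blob
*density* (3:1 by default, Poisson counts), i.e. texture granularity
rather than color alone, so both the GLCM baseline and a convolutional
path can see it. The default cohort shape is 29 short-survival versus
51 long-survival images, matching the class imbalance the evaluation
harness must handle.

**Feature vectors.** Length-2048 Gaussian vectors (the ResNet-101
contract) in which the long-survival class is shifted by `effectSize`
within-class standard deviations on a fixed random 25% of coordinates,
with within-image correlation 0.2 induced by a shared latent factor.
The default effect size is 2 — a strong but not trivial signal: after
compression to 13 sorted cluster centers the class difference survives
as a shift in the upper centers, which is exactly the kind of
distributional signature the FRP stage encodes. Effect size 0 is the
null configuration used to check that the harness leaks no label
information.

What the generators deliberately do **not** emulate: stain
deconvolution physics, spatial correlation structure of real tissue,
scanner variation, or any relationship between texture and actual
survival. A passing end-to-end test therefore demonstrates that the
pipeline recovers class structure that survives its own
representation, and that its cross-validation is leak-free — not that
the method attains any particular accuracy on clinical images.

## Numerical choices and degenerate inputs

- FCM convergence uses the maximum absolute elementwise membership
  change; the objective trace is recorded and is non-increasing, which
  the tests assert.
- The FRP diagonal is set to exactly 1: raw max–min composition gives
  max_k mu_ik ≤ 1 on the diagonal, and reflexivity wins by definition.
- FRPs are stored and serialized as real-valued matrices; the 8-bit
  PNG export (`round(255 F)`) is lossy and for visualization only.
- Prediction ties at exactly 0.5/0.5 resolve to the positive
  (longer-survival) class, documented and tested.
- Metrics with zero denominators (no positives predicted, an empty
  class) are NaN with a warning, never a silent 0.
- Stratified folds deal each shuffled class round-robin with a fold
  counter that continues across classes, so per-fold class counts and
  per-fold totals both stay within one sample of proportionality.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at desk scale, chosen so
the full battery completes in minutes on one core: FCM oracle
comparisons on ≤ 10 points; FRP algebra on 100 seeded instances of
12–16 scalars; backbone forward passes on a handful of small images;
and one full end-to-end experiment per arm (effect size 2 and 0) at
the default 29/51 cohort with 10-fold cross-validation. Larger cohorts
and image counts scale linearly through the same entry points.

## Known limitations

- Random-weight backbones preserve architecture and determinism, not
  trained feature quality; clinical-grade features require loading
  pretrained weights through the extension hook.
- The FRP representation discards the order of the original feature
  coordinates by design (sorted centers); signals encoded purely in
  coordinate identity, with no distributional footprint, are invisible
  to it.
- Single-seed FCM can settle in different local minima under different
  seeds; the pipeline's determinism contract is per-seed, not
  global-optimum.
- The LSTM training path is full-batch on cohort-scale data; very
  large datasets would want minibatching (supported) and possibly a
  lower learning rate.
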