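---
title: "Methods: weakly supervised slide-level prediction with moma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised slide-level prediction with moma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moma` implements a weakly supervised pipeline for predicting slide-level
molecular labels and right-censored survival from H&E histology, together
with occlusion-based explanations. This vignette documents the models, the
numerical choices, and the places where the design was genuinely open — and
what the synthetic test material does and does not demonstrate.

## Pipeline overview

A slide passes through six stages:

1. **Tiling** (`tile_slide`): non-overlapping fixed-size patches (1000 px in
   whole-slide practice; the synthetic material uses 32 px). Partial edge
   tiles are discarded so the feature extractor always sees a fixed input.
   Tiles are flagged background when at least 75% of their pixels have HSV
   saturation below 0.05; both thresholds are package defaults, chosen as
   conventional values for H&E tissue detection.
2. **Stain normalization** (`estimate_stain_profile`, `normalize_tile`):
   Macenko's method. Pixels are mapped to optical density
   `OD = -log10((v + 1) / (I0 + 1))` (base 10, +1 offset so a 0-valued pixel
   stays finite; illuminant 255 per channel matching 8-bit convention).
   Transparent pixels (any channel below `od_beta = 0.15`) are dropped, the
   OD cloud is decomposed by SVD, pixels are projected on the top-2 plane,
   and the directions at the 1st and 99th angle percentiles become the stain
   vectors, sign-corrected and unit-normalized. Hematoxylin is, by package
   convention, the column with the larger blue-channel component — a
   deterministic ordering rule, not a biological claim. Per-pixel
   concentrations come from an exact two-variable nonnegative least squares;
   robust maxima are their 99th percentiles. Normalization rescales each
   stain's concentrations by the ratio of reference to source maxima and
   recomposes with the reference vectors.
3. **Feature extraction** (`extract_features`): a frozen backbone maps each
   tissue tile to a `d`-vector. The shipped backbones are deterministic
   fixed-seed random convolutional extractors (zero-mean random 3x3 filter
   bank on the gray channel, ReLU, global mean/sd pooling, channel
   statistics, then a fixed random affine projection): `default` with
   d = 2048 — the production contract dimensionality — and `tiny` with
   d = 16, which runs the whole pipeline on CPU in seconds and is used by
   every test. A pretrained convolutional network can be plugged in through
   the same `backbone_spec` interface; nothing downstream changes. Tiles are
   resized bilinearly to the backbone's input side. Features are then
   z-scored per dimension on the training tiles (`fit_feature_scaler`):
   backbone statistics share a large common offset across tiles, and without
   standardization the slide-level class signal is a fraction of a percent of
   embedding magnitude, which stalls optimization.
4. **Microenvironment clustering** (`fit_clusters`): k-means (Lloyd, k-means++
   seeding, 5 restarts, fixed seed) with K = 10, mirroring the ten region
   types with biological significance in colorectal pathology. Clustering is
   fit globally on training tiles and applied to all slides; per-slide
   clustering would break the cross-slide identity of clusters that both the
   per-cluster transformer streams and the instance loss rely on. Cluster
   naming is positional, never matched to specific region types.
5. **MIL model** (`mil_forward`): tile features are reduced to 512 dimensions
   by a learned affine map; each nonempty cluster's tiles form a token
   sequence through a transformer encoder (512 hidden, 8 heads, 2048-wide
   MLP, dropout 0.1, 2 layers by default — the encoder depth is not fixed by
   the architecture description we follow, so it is a configurable with
   default 2); gated attention (tanh branch times sigmoid gate, softmax
   normalized) pools tokens to a cluster vector and cluster vectors to the
   slide embedding; an affine + softmax head classifies. Two-level pooling is
   our resolution of "encode per cluster, predict per slide" — the wiring is
   not dictated by the task, and a single-level alternative would not expose
   cluster attention for instance supervision. Positional encodings are
   omitted: tiles are an unordered set, and the forward pass is permutation
   invariant. Per-tile attention is reported as within-cluster weight times
   cluster weight, so it sums to one over the bag.
6. **Heads and losses** (`losses`, `survival`): see below.

## The dual objective

The bag loss is weighted cross-entropy, `-w_y log p_y`, with inverted class
weights `w_c = N / (C n_c)` computed over per-class tile totals, so minority
classes are not drowned out. The instance loss ranks the cluster attention
weights, pseudo-labels every tile of the top three clusters positive and of
the bottom three negative (with fewer than six nonempty clusters both counts
shrink symmetrically), and applies a smoothed hinge

\[ \ell_\tau(z) = \tau \log(1 + e^{(1 - z)/\tau}), \]

which upper-bounds the hinge and converges to it as `tau -> 0+`. The margin
is `z = s_y - max_{c != y} s_c` on the head's per-tile logits (one-vs-rest;
the plain score difference for binary tasks), negated for pseudo-negative
tiles; `tau` defaults to 1 and is exposed per task. The total loss is the
unweighted sum of bag and instance terms. Cluster selection and the
runner-up class are discrete and treated as constants during
backpropagation, the standard subgradient treatment.

## Survival model

A linear head maps an embedding (or covariates) to Weibull parameters through
domain-guaranteeing activations: `lambda = exp(a)`, `kappa = softplus(b)`.
The right-censored negative log-likelihood is

- event: `-[log(kappa/lambda) + (kappa - 1) log(t/lambda) - (t/lambda)^kappa]`
- censored: `(t/lambda)^kappa`

The **survival index** is the predicted median
`lambda * log(2)^(1/kappa)`; the index is otherwise undefined by the
architecture description we follow, and the median is the natural choice
(the Weibull mean is available behind a switch). Cohorts are stratified at
the median index of the *training* fold, applied frozen to held-out data to
avoid leakage. The head is fit with BFGS on the summed NLL (activations
clamped during line search); the production schedule (RMSprop, lr 1e-5,
5 epochs, batch 1) is recorded in `train_config("survival")` for the
end-to-end model.

## Training

`train_classifier` follows the production schedule: SGD with momentum 0.9,
weight decay 5e-4, batch size one slide, cosine-annealed learning rate
(default 1e-3, 250 epochs), best checkpoint selected by validation AUROC
(the selection criterion on the validation set was an open choice; AUROC for
classification and c-index for survival are ours). Gradients are globally
norm-clipped at 1 — standard for batch-size-1 transformer training. Splits
are slide-level and stratified by label (60/20/20 by default, floor rounding
to validation/test, remainder to train, redraw when a class misses a
partition), so no slide's tiles ever span partitions.

All trainable components run on a small reverse-mode automatic
differentiation engine inside the package (`R/autodiff.R`), written for this
model family and verified against central finite differences in the test
suite.

## Interpretation

Occlusion importance of a region (tile) is the signed change in the
predicted target-class probability when the region's tiles are removed from
the bag — for a model that consumes tile features, bag removal is the
faithful analogue of occluding the region's pixels (a pixel-graying mode
would be a parity experiment, not the default). A single-tile slide is
compared against the uniform prior. Because the probability change of a
single tile rarely reaches 0.7 on the raw scale, region selection for
concept scoring uses min–max-normalized importance by default, with the raw
signed scale behind a switch; the 0.7 threshold itself is kept. Concept
scores are importance-weighted sums of the seven concept probabilities over
selected regions, scaled so the maximum is 100; an empty selection yields
all zeros with a warning. The concept classifier is a fixed random 3x3
convolutional filter bank plus channel/edge statistics feeding a multinomial
logistic head (`nnet::multinom`) under a fixed seed. Heatmaps map signed
importance through a blue–white–red diverging palette, alpha-blended over
the slide with a legend bar.

## Synthetic study material

The generators in `synthetic_slides` define the package's study conditions:

- **Textures** are procedural — distinct dot densities, stripe frequencies,
  blob sizes per concept — deliberately not photorealistic: tests need
  determinism and linear separability in simple filter statistics, which the
  acceptance suite verifies (a linear classifier on channel means/variances
  and edge density reaches over 99% held-out accuracy).
- **Slides** are composed in OD space as `stain_matrix x concentrations`
  plus Gaussian OD noise, inverted to 8-bit RGB against illuminant 255. The
  lymphocyte texture contains pure-hematoxylin pixels and the stroma texture
  pure-eosin pixels, giving the Macenko estimator clean angle extremes.
  Stain-recovery fixtures plant matrices whose entries all exceed 0.25: the
  `od_beta` filter drops any pixel with a channel below 0.15 OD, so a stain
  vector with a near-zero channel (like classic eosin's 0.07 red component)
  loses exactly its pure pixels and cannot be recovered to cosine 0.999 —
  a property of the estimator, not a defect of the fixture. The fixed-point
  (idempotence) tests use the same fixture family as their reference, since
  re-estimating a profile from a normalized output is itself a recovery.
- **The planted cohort** (60 slides, 6x6 grid of 32 px regions) labels a
  slide positive iff it carries at least `m = 3` tumor-texture regions;
  positive slides receive 3–6, negative slides none. Attention pooling is a
  weighted mean and therefore count-invariant: a cohort whose negatives also
  contain tumor regions poses a counting task that no attention-MIL model
  can represent, so the planted weak-label signal is presence, not count.
  Tiny-pipeline training uses RMSprop at lr 1e-3 with validation every epoch:
  under batch-size-1 SGD the 16-dimensional architecture trains unreliably
  across seeds (the class signal is small relative to the common embedding
  component), while the adaptive step equalizes the two scales and converges
  within a few epochs for every seed tried. These are choices for the tiny
  architecture, not the production one, whose schedule keeps the SGD
  defaults above.
- **Survival cohorts** draw covariates i.i.d. standard normal and event
  times `Weibull(shape = kappa, scale = lambda0 * exp(coef . x))`; censoring
  is uniform on `(0, q)` with `q` calibrated by deterministic bisection on
  the drawn event times to hit the target censoring rate. The recovery
  conditions are n = 1000, kappa = 1.5, coef = 1.2, 30% censoring.

Passing on this material shows the algorithms are implemented correctly and
the optimization behaves; it does not show that the defaults transfer to real
whole-slide cohorts, where staining, magnification, label noise and biological
heterogeneity dominate and a pretrained backbone is indispensable.

## Degenerate inputs and numerical choices

- Fewer than two usable OD pixels, or a rank-deficient OD cloud (singular
  value ratio below 1e-8), raise an explicit "insufficient stain signal"
  error; the CLI falls back to the shipped reference profile with a warning.
- Background-only tiles pass through normalization unchanged (flagged).
- Nearest-centroid ties break to the lowest cluster index; attention-ranking
  ties to the lowest cluster index.
- Log arguments are clamped at 1e-12; softmax subtracts the row maximum;
  softplus is computed in its overflow-safe form.
- All randomness flows through locally scoped seeds (`with_seed`), so every
  generator, fit and training run is reproducible; training determinism
  additionally assumes single-threaded BLAS, the test-suite setting.

## Known limitations

- No pretrained backbone ships with the package; the `default` backbone
  satisfies the 2048-dimension contract but carries no transfer-learned
  semantics.
- The transformer depth, the two-level pooling wiring, the margin definition
  of the instance loss and the survival-index definition are this package's
  resolutions of genuinely open design points, each documented above.
- Pyramidal WSI containers (SVS/NDPI) are out of scope: flat TIFF/PNG only.
- One model per task; no multi-label heads, no ensembling, no Cox or
  competing-risks alternatives.
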