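---
title: "Brain-age prediction on synthetic phantoms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`brainagekit` implements a hierarchical brain-age prediction pipeline:
conventional machine-learning baselines on engineered features establish
which inputs carry age information, and an ensemble of 3D residual
convolutional regressors with bias-aware regularization produces the final
prediction. This vignette documents the models, their assumptions, every
tunable parameter that matters, and the design decisions taken where the
design was genuinely open.

## The phantom generator: what it emulates and what it does not

Real multichannel structural MRI (a T1 image plus modulated/unmodulated
gray- and white-matter segment maps) cannot be bundled with a package, so
all testing runs on synthetic phantoms from `phantom_config()` /
`make_cohort()`.

* **Age distribution.** Chronological ages are drawn from a log-normal
  distribution truncated to `[age_min, age_max]` (default 17–90 years) and
  calibrated by moment-matching (`optim` over the truncated moments) so the
  *truncated* distribution hits the requested mean and SD — by default
  36.41 ± 16.37 years. The right skew reproduces the thinning of
  middle-to-late adulthood typical of volunteer cohorts, which is exactly
  the regime where regression-to-the-mean bias matters.
* **Anatomy.** The "brain" is an interior ellipsoid (92% of each
  half-axis) tiled into `n_parcels` contiguous parcels by nearest-centroid
  assignment of seeded centroid voxels. Default desk grid 24×28×24 voxels
  at 1.5 mm (a scaled-down analogue of the full 121×145×121 grid, which
  remains available through the config).
* **Signal.** Within parcel *p* of channel *c* a subject of age *a* has
  mean intensity `baseline(c, p) + slope(c, p) · (a − age_mean)` plus
  i.i.d. Gaussian voxel noise (`noise_sd`, default 0.05 in baseline units
  of ~1). Default per-year slopes are drawn once per config from channel
  scales (gmd −0.006, gmv −0.004, wmd −0.003, wmv −0.002, t1 −0.0015 per
  year, each with a ±50% per-parcel spread); density channels age faster
  than volume channels so a density-beats-volume ordering *can* emerge
  downstream, without asserting it as biology. The stub FLAIR channel
  carries no age signal at all: it stands in for a synthesized auxiliary
  modality purely so that four-channel model recipes are exercisable.
* **Determinism.** Each subject's noise stream is seeded by a hash of
  `(config seed, subject_id)`, so a cohort is a pure function of its config
  and is order-independent: rendering subject 7 alone gives bit-identical
  voxels to rendering it inside the cohort.

What phantoms deliberately lack: realistic anatomy, site/scanner effects,
registration error, lesions, and any nonlinearity of ageing. Passing tests
therefore demonstrate that the pipeline recovers a *planted, essentially
linear* age signal under Gaussian noise — they validate the implementation
and its contracts, not clinical-grade accuracy on real MRI.

## Preprocessing

`rescale_fit()` computes one divisor per channel — the maximum voxel value
over all *training* subjects — and `rescale_apply()` divides by it,
mapping training data into [0, 1]. Held-out subjects reuse the stored
divisor; values above it are clipped to 1, keeping the [0, 1] contract at
the cost of saturating rare extreme voxels (the alternative, leaving them
>1, would leak an unbounded scale into the network). Rescaling is
per-channel rather than global because the channels live on unrelated
intensity scales. `conform_grid()` resamples trilinearly with voxel-center
alignment and zero padding outside the source field of view.
`stack_channels()` concatenates channels into the 4D `(channel, x, y, z)`
input in configured order.

## Feature extraction

**Parcel-wise.** `parcel_means()` averages voxels per atlas label
(ascending label order); with the full 442-parcel composite atlas and two
tissue channels this yields 884 features. The operator is linear, which
the tests exploit as an invariant.

**Spatial ICA.** `fit_spatial_ica()` decomposes a subjects × voxels matrix
into K spatial components: voxel-wise centering, PCA whitening to K
dimensions, then symmetric FastICA with the logcosh contrast
(`tol = 1e-4`, `maxit = 500`, random orthogonal initialization from the
seed; component signs fixed to positive skewness). On data whose leading
subspace is near-Gaussian the symmetric iteration can cycle rather than
settle; the fit then returns the minimum-step-change iterate with
`converged = FALSE` and a warning — a legitimate basis, just not a fixed
point. `integrity_scores()` regresses a subject's masked voxel vector on
all K maps *jointly* (with intercept), the dual-regression convention;
K marginal regressions would ignore component correlations. Bases are fit
on training subjects only and applied frozen elsewhere; the ICA mask keeps
voxels nonzero in ≥95% of training subjects. Desk default K = 20 per
channel; the full-scale value is 400 (×4 tissue sets = 1,600 features).

## Conventional ML baselines

`nested_cv()` runs the canonical protocol: 10 outer folds; in each outer
training split, a 10-fold inner grid search scored by mean negative MAE
picks λ (ridge: {0.001, 0.01, 1, 10, 100}) or C and γ (RBF-SVR:
{0.001, 0.01, 0.1, 1, 10, 100, 1000} each); the model is refit on the
outer-train split and the outer-test fold predicted, so every subject is
predicted exactly once. Pooled MAE/RMSE/R² are computed on those
out-of-fold predictions. Design choices: features are z-scored within each
training split (SVR-RBF is scale-sensitive; without standardization a
fixed γ grid is meaningless), folds are randomized from the config seed
without age stratification, SVR ε stays at the conventional 0.1, and ties
in the grid go to the earliest grid entry. Ridge is solved in closed form
with an unpenalized intercept; `fit_final()` re-runs the inner search on
the full training sample, refits, and stores the feature-name schema so
prediction aligns columns by name and refuses incomplete tables.

## The 26-layer residual regressor

`resnet_spec()`/`resnet_build()` define: stem 3×3×3 convolution → 12
residual blocks → global average pooling → one linear unit (26 weighted
main-path layers; shortcut projections sit off the main path). Each block
is conv–BN–ReLU–dropout–conv–BN with an additive shortcut and final ReLU.
Blocks 4, 7 and 10 use stride 2 (axes must be divisible by 8) with a 1×1×1
stride-2 convolution + BN on the shortcut. Widths double at each stride-2
stage; the full-scale stem is 16 (16/32/64/128), the desk default divides
widths by 4. Dropout sits between the two convolutions (default 0.1); with
`sex_input` a 0/1 scalar joins the pooled vector before the linear layer.
Ages are regressed in years, unnormalized, so losses read directly in
years.

Training (`train_resnet()`) is plain SGD: lr 0.1, momentum 0.9, weight
decay 5e-4 on all parameters, batch 8, tenfold LR drops after 50% and 75%
of the epochs, 300 epochs at full scale. Every epoch logs a checkpoint
record (validation MAE and the Spearman correlation of delta with age);
the minimum-validation-MAE record is flagged. Non-finite losses or
predictions abort with the epoch index. Batch norm uses ε = 1e-5 and
running-stat momentum 0.1; early-epoch validation error is dominated by
the running statistics still converging, which is why desk-scale runs need
a handful of epochs before the curves become meaningful.

## The regularization losses

For a mini-batch of N subjects with ages Y and predictions Y′, with
E = Y′ − Y:

* covariance loss `L_cov = (1/N) Σ_ij (E_i Y_j)² = (1/N) ||E||² ||Y||²`,
* ranking loss `L_rank = (1/N) Σ_ij (Y′_i Y′_j − Y_i Y_j)²` — the squared
  Frobenius difference of the predicted and true Gram matrices.

Both are non-negative, zero at perfect prediction, and differentiable in
Y′ (`L_cov` also vanishes in the degenerate all-zero-age batch). The
notational reading — 1/N times the sum over *all* N² entries of the
matrix — keeps the 1/N prefactor and the matrix-valued inner expression
coherent; the tests pin it to an independent double-loop oracle. The
composite loss is MAE plus `reg_weight` times the chosen regularizer. The
default `reg_weight = 1e-6` makes the terms comparable at initialization:
for age-scale batches (N = 8, ages ≈ 36 ± 16) both regularizers start
near 2×10⁷, so 1e-6 scales them to the same order as the initial MAE
(~30 y); substantially larger weights make the cubic-in-Y′ ranking
gradient overwhelm SGD at lr 0.1. The plain-MAE mode is the first,
unregularized member configuration; "second regularization" in the
member recipes refers to the ranking loss.

## Ensembling and checkpoint selection

`median_aggregate()` takes the per-subject median across member
predictions (even counts: mean of the central pair) — permutation-
invariant and bounded by the member min/max. `objective1_members()`
enumerates the five member recipes (T1+GMV+WMV; +ranking loss; +sex;
T1+GMD+WMD; +stub FLAIR). `select_checkpoints_objective2()` filters a
checkpoint pool to validation MAE < 3.8 y **and** |ρ| < 0.1, sorts by MAE
with |ρ|, config and epoch as tie-breaks (a total order, so selection is
independent of input order), and keeps the top 8. The threshold applies to
|ρ| because delta-age correlations are routinely negative; several
selected checkpoints may come from the same training run, since the pool
is per-epoch. Selection metrics come from the designated validation split.

## Evaluation and bias correction

`metric_report()` gives MAE, RMSE, R², Spearman ρ of delta vs age, and
KLD(P‖Q) between the chronological (P) and predicted (Q) age histograms.
KLD uses 5-year bins spanning 15–95 years, natural logarithm, additive
smoothing ε = 1e-6 on both histograms before normalization, and clamps
out-of-range values into the edge bins; histogram KLD was chosen over
kernel density estimates as the simplest estimator with an exact
closed-form check. With few validation subjects the histograms are sparse
and KLD is accordingly large and noisy — it is most meaningful at cohort
scale. `fit_bias()` regresses delta on age by OLS on training predictions
(the delta-residualization direction of the standard correction);
`apply_bias()` subtracts the fitted line, which makes corrected delta
exactly orthogonal to age on the fitting set and, when the bias structure
generalizes, pulls held-out |ρ| below the Objective-2 threshold.

## Pipeline, problem sizes and reproducibility

`run_pipeline()` chains simulate → preprocess → features → train_ml →
train_dl → ensemble → evaluate under one run directory with a manifest
(config hash, seeds, stage status). One global seed fans out to per-stage
streams through the same string-hash mechanism as the phantom generator,
so a config reproduces its run bit-for-bit. The desk-scale defaults — 60
subjects on a 16³ grid, 24 parcels, K = 8, two residual-net members at
stem width 4 for 8 epochs — were chosen as the smallest sizes at which
every stage still has recoverable signal (ridge R² ≈ 0.97 on held-out
phantoms, residual nets clearly below the null MAE after a few epochs);
the published full-scale values stay in the config as documentation. The
tests use the same or smaller sizes; the acceptance script trains the
standard desk benchmark (120 phantoms, 16³, 30 epochs) where the network
reliably beats the null predictor by a wide margin.

## Known limitations

* The residual-net engine is single-threaded CPU code built for desk-scale
  grids; full-scale (121×145×121, 300 epochs) training is out of its
  practical range.
* FastICA on phantom cohorts often returns a flagged best iterate rather
  than a converged fixed point (see above); component order is arbitrary
  as in any ICA.
* The Objective-2 MAE/ρ thresholds are tuned to real-cohort error scales;
  on tiny phantom runs they may select nothing, in which case the
  selection returns empty with a warning and the caller decides.
* The bias correction assumes a linear delta–age relationship; curvature
  in the bias would need a flexible regressor in `fit_bias()`.
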