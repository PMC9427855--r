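---
title: "Mapping tau-PET topography to amyloid Centiloid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tau-PET topography to amyloid Centiloid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taucl)
```

## The scientific problem

Amyloid-beta (A&beta;) burden is routinely summarized as a scalar Centiloid
(CL) value, while tau pathology is imaged as a full 3D PET volume. `taucl`
implements a pipeline that learns a nonlinear mapping from the tau volume to
CL with a compact 3D convolutional network and then *interprets* that
mapping: which voxels carry the information (gradient saliency + voxel-wise
GLM with family-wise error control), how much unique information each
significant cluster holds (occlusion, post-occlusion out-of-sample
R&sup2;), and how a region's importance changes along the CL continuum
(LOESS-smoothed "strength of association" curves). Because real tau-PET
cohorts are access-restricted, the package ships a synthetic phantom
generator that plants the statistical structure the analysis is meant to
find, so every stage is testable end to end from code alone.

## The synthetic phantom

`synthetic_config()` defines the study conditions. A cohort of `n_subjects`
(default 150) receives a Centiloid value uniform on `[cl_low, cl_high]`
(default [-10, 140]), a normal age (71 ± 7.7 y) and a Bernoulli(0.5) sex;
train/validation/test assignment follows the 109/12/13 proportions of a
134-subject tau-amyloid cohort. Volumes (default 32×40×32 voxels at 2 mm;
the full 158×198×158 at 1 mm is a configuration, not a default — the desk
grid trains on one CPU in minutes) contain, inside an ellipsoidal brain
mask:

* a **low-CL effect region** ("FPC-like", fronto-parietal/cingulate
  analogue) whose intensity is `baseline + effect_low_region * g_low(cl)`
  with `g_low` a linear ramp from `cl_low` that saturates at the
  changepoint (default CL 25, also the descriptive A&beta;-positivity
  threshold);
* two **high-CL effect regions** ("MT-like", medial-temporal analogue,
  left/right) following `g_high`, a *smooth hinge*: a softplus
  `log(1 + exp((cl - changepoint)/tau))` (scale `logistic_tau_cl`, default
  5 CL), shifted and normalized to [0, 1] over the cohort CL range. Its
  derivative is the logistic sigmoid, so the ramp is sigmoidal: nearly
  flat below the changepoint and nearly linear above it;
* two **null regions** and unlabeled in-mask tissue at `baseline` with no
  CL dependence;
* a **CL-independent off-target region** ("meninges-like", amplitude
  2.0 SUV over baseline), emulating the strong off-target binding of
  first-generation tau tracers;
* i.i.d. Gaussian voxel noise (`noise_sd`, default 0.1 SUV), truncated at
  zero.

Three design points deserve explanation.

**Why a smooth hinge rather than a logistic CDF for `g_high`.** A logistic
CDF with a scale small enough to be flat below the changepoint saturates
early (with scale 10 CL it is flat above CL ≈ 65), leaving the upper half
of the cohort unidentifiable from the images — the network then cannot map
the full CL continuum. A scale large enough to reach CL 140 is no longer
flat below the changepoint, and the low-CL region loses its informational
monopoly there — the network then simply ignores it (occluding it changes
R&sup2; by < 0.01) and no importance crossover exists to recover. The
normalized softplus is the simplest form with both required properties: at
scale 5 CL, the low-CL region's intensity slope dominates the high-CL
regions' by a factor ≥ 6 throughout CL < 20, while above the changepoint
the ramp rises essentially linearly to `cl_high`.

**Why the off-target region exists.** The network input is each image
min-max scaled to [0, 1] (brain-mask voxels only). If the image maximum
were set by the planted effect regions it would grow with CL, and *every*
scaled background voxel — nominally free of CL signal — would carry CL
information through the normalization denominator; pilot networks happily
exploited that shortcut and their saliency spread over the whole brain. A
fixed high-uptake structure (as off-target tracer binding provides in real
scans) pins the image extrema to CL-independent values, so the scaled
background is genuinely null, as the phantom's design intends.

**What the phantom does not emulate.** PET noise physics, partial-volume
effects, anatomical realism, spatial noise correlation, and — importantly —
inter-subject biological variability of tau burden at fixed CL. The last
omission makes the phantom far cleaner than real data; consequences for
the saliency analysis are discussed under *Limitations*.

## Preprocessing

`minmax_scale()` rescales in-mask intensities to [0, 1] (background stays
0; a constant image yields zeros plus a warning rather than an error so
batch runs survive). `compute_suvr()` divides by the mean over the
cerebellar-like reference region, the conventional SUVR normalization used
for the linear comparison analysis. `gaussian_smooth()` implements
separable Gaussian smoothing parameterized by FWHM in mm
(`sigma = fwhm / (2 sqrt(2 log 2))` per axis, in voxels); at grid edges the
truncated kernel is renormalized over its in-grid support — no wrap-around
and no leakage of mass into the background, so saliency mass near the mask
edge is not drained. The kernel is truncated at 4 sigma.

## The CNN regressor

`cnn_config()` defaults to an encoder in the spirit of the contracting half
of a U-net: four 3×3×3 convolution stages with stride 2 and channel widths
8/16/32/64, ReLU activations, global average pooling and a 32-unit dense
layer before the scalar output. Softplus activations and a position-aware
`flatten` head are available alternatives. Training minimizes mean squared
error with RMSprop (lr 3e-3, rho 0.9, batch 24) plus an L2 weight penalty
(1e-4) on convolution/dense weights; the CL target is standardized to the
training split internally and predictions are always returned in CL units.
The epoch with the best validation RMSE is kept (early stopping, patience
20, at most 100 epochs; best epochs observed on the default phantom are
23–65). Everything — initialization, batch order, the whole compute path —
is plain deterministic R, so a fixed seed reproduces predictions exactly.

Cross-validation follows `make_folds()`: the held-out test set is fixed by
the cohort split; non-test subjects are partitioned into K near-equal
validation blocks (paper-scale K = 10; the desk default is K = 3, which on
the default phantom trains in ≈ 4 minutes on one CPU). The best instance
minimizes the mean of validation and test RMSE, with ties broken toward
the lowest fold id. Out-of-sample R&sup2; is `1 - SS_res/SS_tot` with the
evaluation split's own mean as baseline (the alternative training-mean
baseline can be passed explicitly); it is negative whenever predictions do
worse than that mean, which occlusion routinely produces.

On the default phantom the best instance reaches validation R&sup2; ≈ 0.99.
A k-nearest-neighbour / GAM oracle given the *ideal* planted region means
attains the same validation RMSE, i.e. the network sits at the phantom's
information ceiling rather than underfitting.

## Saliency

`compute_saliency()` backpropagates a unit output gradient through the
network to obtain the exact derivative of the predicted CL with respect to
every input voxel, evaluated at the observed input, and takes its absolute
value (signed maps via `absolute = FALSE`). `prepare_saliency()` masks to
the brain and smooths with a 2 mm FWHM kernel. Gradient fidelity is
verified against central finite differences on random small networks
(smooth activations; for ReLU networks finite differences are only
informative away from the activation kinks, which the tests respect).

## Voxel-wise GLM, permutation FWE, clusters

The design matrix is intercept + CL + age + sex; the t-contrast tests the
CL coefficient (two-sided by default — saliency can decrease with CL in
low-CL-informative regions; a positive-tail option exists). OLS is fit at
every voxel by the normal equations; numerically exact fits are flagged
and given infinite t.

Family-wise error control uses Freedman–Lane permutation of the maximum
statistic: the data are residualized against the nuisance covariates, the
residual rows are permuted, the nuisance fit is added back, and the full
model is refit; the threshold is the `floor(alpha*(B+1))`-th largest of B
permutation maxima, an exactly level-`floor(alpha*(B+1))/(B+1)` procedure
under exchangeability (0.05 at B = 199, alpha = 0.05). Cohorts too small
for B distinct permutations are enumerated exhaustively. Suprathreshold
voxels are grouped by 26-connectivity (6/18 selectable) and components
below the extent threshold are discarded. The extent criterion is
volumetric in spirit: 200 voxels at 1 mm&sup3; is converted to an
equal-volume voxel count at the working resolution (25 voxels at 2 mm).

**Global normalization.** Gradient saliency maps carry an arbitrary
per-subject global scale; empirically that scale covaries with CL (the
network's output sensitivity changes along the continuum). Left in place,
it inflates associations at null voxels *and* can cancel true regional
ones — on the default phantom the raw median t in the high-CL regions was
−0.4 versus +5.5 after normalization. The pipeline therefore defaults to
proportional scaling (each map divided by its in-mask mean, the classic
SPM global-scaling analogue) with ANCOVA (global mean as nuisance) and raw
fits selectable.

Cross-instance consistency is summarized by pairwise Dice overlap of the
binarized cluster masks and a per-voxel consensus count.

## Occlusion and strength of association

`occlusion_r2()` recomputes predictions with a cluster replaced by a fill
value, the network untouched, and reports per-split R&sup2; before and
after. The **fill** matters: zeroing a region (fill 0) pushes the input far
off the training manifold, so the prediction change measures the sheer size
of the perturbation rather than the region's information — the
high-amplitude MT-like region then dominates at every CL and no importance
crossover can be seen. The default is therefore a **tau-naive template**:
the voxel-wise mean image of the lowest-CL decile of the cohort. Occluding
with it erases disease-related information while keeping the input
plausible; for subjects whose region carries no signal it is nearly a
no-op, which is exactly the semantics "remove what this region knows about
pathology". Scalar 0, cohort-mean and A&beta;-negative-mean fills remain
available for sensitivity analyses.

`strength_of_association()` computes, per cross-validation instance, the
absolute difference between predictions on full and occluded inputs for
every subject (splits pooled), smooths it against measured CL with LOESS,
and averages across instances with the standard error of the mean. The
LOESS (`loess_smooth()`) is local-linear with tricube weights over the
`ceiling(span*n)` nearest neighbours. The default span is 0.3: with 150
subjects over a 150-CL range, span 0.5 is a ±35 CL window that smooths
away structure at the scale of the 25-CL changepoint, while 0.3 resolves
it; the span is recorded in every curve object. Curves are clamped at zero
(the underlying errors are nonnegative). The dominance changepoint is
estimated as the *last* crossing of the high-CL over the low-CL curve —
earlier sign flips can occur in the near-zero tails where both curves are
small. On the default phantom this crossing lands within a few CL of the
planted changepoint 25. `split_subclusters()` partitions a cluster by the
atlas parcels (background voxels forming a `"residual"` sub-cluster) for
sub-cluster curves.

## Orchestration and reproducibility

`pipeline_config()` + `run_pipeline()` chain
generate → preprocess → train → saliency → GLM → occlusion with a single
master seed fanned out to named sub-seeds (`derive_seed()`), so any stage
is re-runnable in isolation and two runs with the same configuration are
bit-identical (training included — there is no nondeterministic compute
path). Stage toggles are honored in dependency order; a stage whose inputs
are missing halts with an error naming the missing stage.
`evaluate_recovery()` scores a full run against the generator's ground
truth (cluster coverage and Dice of the planted regions, null-region
containment, post-occlusion collapse, curve crossing), and
`estimate_fwer()` Monte-Carlo-checks the permutation threshold's
calibration on pure-noise stacks.

Problem sizes used by the shipped tests and the acceptance script: the
default phantom (150 subjects, 32×40×32 at 2 mm), K = 3 folds, 499
permutations for recovery runs; FWER calibration at 30 subjects × 400
voxels × 500 replicates × 199 permutations.

## Numerical choices

* Min-max scaling statistics come from brain-mask voxels only; constant
  images scale to zeros with a warning.
* Smoothing boundary: per-axis renormalized truncated kernels (no wrap, no
  zero-leak); kernels truncated at 4 sigma.
* Exact voxel fits (residual sum of squares at round-off level) get
  infinite t and are counted, not propagated as NaN.
* Permutation thresholds use the k-th-largest order statistic with
  `k = floor(alpha*(B+1))`, giving exact finite-sample level under
  exchangeability; `alpha = 1` degenerates to the sample minimum.
* Best-instance ties break toward the lowest fold id; cluster ordering is
  by decreasing size.
* Per-subject volume noise streams are derived by hashing the master seed
  with the subject id, so single volumes regenerate independently of
  generation order.

## Limitations

* **Diffuse saliency associations on clean phantoms.** Gradient saliency
  of a convolutional network gives every voxel a nonzero gradient (shared
  kernels, pooling); its subject-to-subject variation inherits the
  CL-dependent internal gating of the network. On a phantom with no
  biological variability the residuals of those weak background
  associations are tiny, so with n = 150 a properly FWE-controlled GLM
  finds 15–35% of background voxels significant; clusters then percolate
  across the background, and the cluster union covers the planted regions
  only partially (coverage ≈ 0.7–0.8, Dice ≈ 0.2 against the planted
  masks) even though no cluster lies fully inside a null region and the
  occlusion analysis attributes essentially all predictive power to the
  planted regions. This is a property of the attribution method in a
  low-noise regime, faithfully reported by the statistics, not a failure
  of FWE control (which the null calibration verifies); on real data the
  much larger saliency residual variance suppresses these weak
  associations. Interpreting saliency clusters should always be paired
  with occlusion, which remains specific here.
* The phantom's region geometry is spherical and its noise white; none of
  the tests say anything about registration error, partial volume, or
  scanner effects.
* R&sup2; after occlusion is a proxy for importance; it attributes no
  causality.
* Retraining with clusters removed from the input (rather than occluding
  at inference) is out of scope.
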