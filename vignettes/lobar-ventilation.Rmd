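---
title: "Lobar ventilation quantification from hyperpolarized-gas time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lobar ventilation quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xelobe)
```

## The problem

In chronic obstructive pulmonary disease (COPD), spirometry gives a single
whole-lung number, while the disease itself is regionally heterogeneous.
Lobar ventilation imaging fills that gap: how much of the lung's gas intake
does each of the five lobes (RUL, RML, RLL in the right lung; LUL, LLL in
the left) actually receive, and how does that relate to structural
emphysema on CT, to SPECT ventilation/perfusion, and to lung function?

Hyperpolarized xenon-129 MRI measures ventilation directly — inhaled
polarized gas is the signal source — but the signal is *non-renewable*:
every RF excitation consumes part of the magnetization, and what remains
relaxes with a time constant T1. On top of that, the receive/transmit coil
makes the effective flip angle vary across the chest. Raw signal intensity
therefore mixes ventilation with acquisition physics. This package
implements the quantification chain that untangles them, exercised entirely
on a synthetic digital thorax phantom with known ground truth.

## The signal model

During a breath-hold time series of `n` volumes, a voxel that has
experienced `P` RF pulses per completed volume (one per spiral interleave)
gives, at volume `k` acquired at elapsed time `t_k`,

$$S_k \;=\; S_0 \,\sin\alpha\; \cos(\alpha)^{P\,(k-1)}\; e^{-t_k/T_1}.$$

Each pulse reads out $\sin\alpha$ of the available longitudinal
magnetization and leaves $\cos\alpha$ of it; T1 relaxation acts on elapsed
time. $S_0$ is proportional to the local ventilation. This is the standard
non-renewable-magnetization form for hyperpolarized gas; wash-in/washout
dynamics outside the breath-hold are deliberately not modelled, because the
quantification operates on the breath-hold series only.

`fit_decay_model()` inverts the model per lobar (or per intensity-bin)
mean curve by bounded Levenberg–Marquardt least squares with the analytic
Jacobian. Initialization is deterministic ($\alpha_0 = 8^\circ$,
$T_{1,0} = 25$ s, $S_{0,0} = y_1/\sin\alpha_0$); bounds are
$\alpha \in (0.1^\circ, 89^\circ)$, $T_1 \in (1, 200)$ s, $S_0 \ge 0$.
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the curve mean.

## Identifiability: when can α and T1 be separated?

With uniform volume spacing $\Delta t$ and constant $P$, the model
collapses to $A\,r^{k-1}$ with
$r = \cos^P\!\alpha\; e^{-\Delta t/T_1}$ — two effective parameters for
three unknowns. Any $(\alpha, T_1)$ pair on the level set of the combined
per-volume decay rate

$$\rho \;=\; P \ln \sec\alpha + \Delta t / T_1$$

fits equally well. `check_identifiability()` makes this concrete: it
evaluates the fit Jacobian at nominal parameters
($S_0 = 1, \alpha = 10^\circ, T_1 = 20$ s), normalizes columns, and
reports the condition number. The cutoff is $10^6$: uniform schedules sit
many orders above it (the Jacobian is numerically rank 2), while usable
non-uniform schedules sit below $10^4$, so any threshold in between
separates the regimes; $10^6$ was fixed once and documented. At least 3
volumes are required regardless (3 unknowns).

Three *non-uniformly spaced* time points are sufficient: the two
log-signal ratios give two independent linear equations in
$(\ln\cos\alpha,\, 1/T_1)$ with an invertible coefficient matrix, and
$S_0$ follows from the first point. Two points are provably insufficient —
a one-parameter family of triples reproduces them exactly (both facts are
asserted in the acceptance tests).

When a fit is non-identifiable the package still returns the ridge fit,
flags it, and reports the combined rate $\rho$, which is exactly the
quantity the decay correction needs; only the α/T1 *split* is non-unique.
The package default schedule for its own pipeline
(`identifiable_schedule()`: volumes at 0, 0.6, 1.2, 2.5, 5, 9, 14, 20 s,
8 pulses each) keeps 8 volumes within a 20-s breath-hold but clusters them
early and stretches them late, condition number ≈ 54.

## Decay correction

`correct_timeseries()` divides each voxel's time course by its region's
modelled decay factor

$$f_k \;=\; \frac{\sin\hat\alpha_r}{\sin\alpha_{ref}}\;
\cos(\hat\alpha_r)^{P(k-1)}\; e^{-t_k/\hat T_{1,r}},$$

then averages the corrected volumes (noise averaging). The factor is
referenced to volume 1 within a region, so with identity decay
($\alpha \to 0$, $T_1 \to \infty$) the output reduces to the plain mean of
the input volumes; the $\sin\hat\alpha_r / \sin\alpha_{ref}$ term removes
coil shading *between* regions ($\alpha_{ref}$ defaults to the median
fitted flip angle). With per-intensity-bin fits
(`intensity_bin_masks()`), a factor-2 anterior–posterior coil gradient on
uniform lungs is flattened to within 2% (asserted in the test suite). The
corrected image is floored at zero by default (`clip_negative`): gas
signal is physically nonnegative, so negative values can only be noise
residues in signal voids, and downstream share formulas require
nonnegative input.

## Lobar scores

Four scores per subject, one row per lobe plus whole lung
(`lobar_score_table()`):

* **CT %emphysema** — percentage of lobe voxels strictly below −950 HU.
  Strict `<` follows the threshold's "less than" definition.
* **Relative %ventilation** (gas MRI and SPECT alike) — the lobe's share
  of total lung signal, $100\,\Sigma_{lobe} S / \Sigma_{lung} S$. The
  denominator is the whole-lung *signal* sum: that is the only
  normalization under which the five lobar percentages sum to exactly 100,
  which is the stated convention of lobar SPECT analysis.
* **Absolute %ventilation (defect) score** — percentage of lobe voxels
  strictly below 5% of a whole-lung reference level. The reference is the
  99th percentile of lung-voxel signal by default (a hot-pixel-robust
  maximum; `"max"` and `"mean"` are available as options). Higher = more
  defect; note the naming tension — the score is called "%ventilation" in
  the field but has defect semantics — which we keep, documented.
* **SPECT %ventilation / %perfusion** — the same share formula on count
  volumes, after nearest-neighbour resampling of the lobe masks to the
  SPECT grid.

## The digital thorax phantom

The phantom states a world in which every downstream claim is checkable:

* **Geometry**: two ellipsoidal lungs (fractions of a 56×56×44 grid at
  4 mm isotropic spacing — a scaled-down adult thorax), cut by oblique
  fissure planes (constant $z + 0.35\,y$) at fixed quantiles into 3 right
  + 2 left lobes. Deterministic; no RNG.
* **CT**: parenchyma HU ~ N(−850, 40), emphysema HU ~ N(−980, 15) — the
  −950 HU cut sits between the modes — and soft tissue N(40, 20) outside
  the lungs. Emphysema occupies the upper tail of a smooth Gaussian random
  field, thresholded per lobe at the target fraction: spatially coherent
  blobs (as emphysema appears on CT), exact voxel-count fractions.
* **Default lobar burden** (15, 18, 29, 18, 25% for RUL…LLL) mirrors the
  lower-lobe-predominant pattern reported for a severe-COPD subject
  (lower-lobe scores of 29% and 25% against 15–18% elsewhere).
* **Ventilation**: smooth field in ≈[0.5, 1] inside the lungs, defect
  regions (≈0.01, far below the 5% threshold) as the lower tail of a
  second smooth field; perfusion uses the same construction with an
  independent stream, so V and Q agree lobarly but not voxelwise.
* **Coil map**: linear in $\sin\alpha$ along the posterior→anterior axis,
  anchored so the first-volume signal ratio across the grid equals
  `coil_ap_ratio` (default 2, the reported surface-coil extreme), with the
  nominal flip angle (10°) at the geometric mean.
* **SPECT**: Gaussian blur to 10 mm FWHM, trilinear integral-conserving
  resampling to 4 mm pixels, scaling to 2×10⁶ expected total counts,
  Poisson noise. Blur+resample conserves expected counts to 0.5%.
* **Noise**: additive zero-mean Gaussian on real-valued images, default
  `noise_sd = 0.003` ≈ first-volume SNR 50 for a well-ventilated voxel at
  10°. In-vivo SNR is *not* a stated property of the protocol, so this is
  a documented free parameter of the phantom, not a literature value. No
  Rician magnitude bias is simulated (negatives kept), which keeps the
  fitter's estimand unbiased and the recovery tests interpretable.
* **Cohort**: subject severity spread evenly over [0.08, 0.85] scales a
  lower-lobe-predominant base pattern with log-normal per-lobe jitter;
  defect burden is an increasing linear function of emphysema burden plus
  noise — so emphysema *drives* ventilation loss by construction — and
  spirometry-like covariates decrease linearly in whole-lung defect
  (FEV1%pred ≈ 95 − 90·defect, FEV1/FVC ≈ 85 − 70·defect, chosen to span
  the GOLD I–IV spirometry range without saturating the physiologic
  floors).

What a green test therefore establishes: that the *pipeline* recovers
known truth — fractions, parameters, shares, sign patterns — under stated
physics. What it does not establish: registration accuracy (all phantom
modalities share a world frame; real data need deformable registration,
for which `resample_mask()` is only the grid-alignment substitute), airway
anatomy, breathing motion, scanner physics, or the patient-cohort
correlation magnitudes, which depend on data we do not have.

## Numerical choices

* Levenberg–Marquardt with diagonal damping, λ ∈ [10⁻¹², 10¹²], step
  acceptance on SS decrease; convergence on relative step < 10⁻¹³,
  relative SS drop < 10⁻¹³, or SS below 10⁻²⁸ of the curve's energy.
  Parameters are clamped to bounds after each step.
* Quantile splits and thresholds use R's type-7 quantiles everywhere.
* Gaussian smoothing is separable with a 4σ-truncated discrete kernel and
  zero padding; SPECT count conservation holds because the lungs sit away
  from the grid edge.
* Mask resampling is pure nearest-neighbour (target-centre containment);
  a lobe vanishing at coarse target resolution is a hard error naming the
  lobe, never a silent drop.
* All randomness is seeded through one `random_seed` per phantom spec and
  derived sub-streams; identical specs give byte-identical outputs.
* Pearson p-values use the t transform on n−2 df, intervals the Fisher z
  transform (SE $1/\sqrt{n-3}$); regressions are plain OLS with the
  textbook slope SE. Pooled lobar regressions deliberately ignore
  within-subject clustering — that mirrors the comparison structure this
  package reproduces — and the limitation is stated rather than silently
  "fixed" with mixed models.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(n_subjects = 12, seed = 1, write_volumes = FALSE)
res <- run_pipeline(cfg, "phantom_run")
print(res$report)
subset(res$scores, subject_id == "S08" & lobe != "whole_lung")
```

The pooled regressions in `res$report` reproduce the expected sign
pattern: emphysema burden correlates negatively with a lobe's relative
ventilation share and positively with its absolute defect score, the two
SPECT shares track the gas-MRI share positively, and whole-lung defect
correlates negatively with the FEV1-like covariates. The acceptance
script (`scripts/acceptance.R`) recomputes the two headline quantities —
the exact sum-to-100 conservation of relative lobar shares and the median
R² (≈ 0.996 at first-volume SNR 50 over 100 replicates, against the
≥ 0.98 regime the fit-quality claim requires) — from scratch at every run.

## Known limitations

* Lobar curve fits assume the decay parameters are homogeneous within a
  region; the intensity-bin mode relaxes this for the coil profile but
  still assumes ventilation-intensity bins track flip angle, which fails
  if true ventilation and coil gradients are strongly correlated.
* The uniform 2.5-s schedule — the protocol this package's defaults
  otherwise mirror — is formally non-identifiable for the α/T1 split in
  this model. How the original protocol separated them (slice ordering,
  supplementary constraints) is not stated in the accessible text; the
  package exposes both regimes and the diagnostic instead of guessing.
* Percentile-referenced defect thresholds couple lobes weakly through the
  whole-lung reference level.
* The phantom's lungs are ellipsoids; fissure geometry, airways and the
  diaphragm are not modelled, so absolute lobe volume shares are not
  anatomically calibrated.
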