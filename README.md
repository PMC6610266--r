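# xelobe

Lobar lung-function quantification for time-series hyperpolarized
xenon-129 MRI, with CT emphysema scoring, SPECT ventilation/perfusion
shares, and cohort comparison statistics — exercised end to end on a
digital thorax phantom with known ground truth.

## Who this is for

Researchers working on regional ventilation quantification in COPD who
need the full analysis chain — signal-decay modelling, flip-angle/T1
estimation and correction, lobar scoring, multi-modality comparison — as
tested, reproducible code that runs without any patient data. Every stage
is validated against a synthetic five-lobe phantom whose emphysema burden,
ventilation defects, coil inhomogeneity and SPECT degradation are known
exactly.

## The model at the core

Hyperpolarized gas magnetization is non-renewable. During a breath-hold
series of volumes (default: 8 volumes in ~20 s, 8 spiral interleaves — and
hence 8 RF pulses per voxel — per volume), the expected signal at volume
*k*, acquired at elapsed time *t<sub>k</sub>*, is

    S_k = S0 · sin(α) · cos(α)^(P(k−1)) · exp(−t_k / T1)

with flip angle α, pulses per volume P, and longitudinal decay time T1.
The package fits (S0, α, T1) per lobe by bounded Levenberg–Marquardt with
the analytic Jacobian, diagnoses whether the acquisition schedule makes
α and T1 separable at all (uniform spacing provably collapses them into a
single exponential; the condition-number diagnostic and a non-uniform
8-point schedule are built in), divides the decay out of the series, and
scores the corrected image:

* **CT %emphysema** — share of lobe voxels below −950 HU,
* **relative %ventilation** — a lobe's share of total lung signal (sums
  to exactly 100 over the five lobes),
* **absolute %ventilation (defect) score** — share of lobe voxels below
  5% of a whole-lung reference level,
* **SPECT %ventilation / %perfusion** — the same share formula on count
  volumes,

then compares them across a phantom cohort with Pearson correlations
(t-test p, Fisher-z 95% CI) and OLS regressions.

## Worked example

```r
library(xelobe)
sp   <- phantom_spec(random_seed = 42)       # one synthetic subject
subj <- generate_phantom_subject(sp)         # masks, CT, V/Q maps, coil, SPECT
res  <- analyze_subject(subj, "S42")         # simulate + fit + correct + score

print(res$fits$RLL)
#> <decay_fit RLL: S0 = 0.5728, alpha = 10.652 deg, T1 = 20.161 s, R2 = 1.00000>

print(subset(res$table, lobe != "whole_lung"), digits = 3)
#>   subject_id lobe ct_emphysema_pct hpx_rel_vent_pct hpx_abs_vent_pct
#> 1        S42  RUL             15.2             20.6             8.98
#> 2        S42  RML             18.2             20.8            10.90
#> 3        S42  RLL             28.9             15.6            25.19
#> 4        S42  LUL             18.1             24.3            10.69
#> 5        S42  LLL             25.1             18.7            20.90
#>   spect_vent_pct spect_perf_pct
#> 1           20.2           20.0
#> 2           21.3           18.7
#> 3           15.7           16.4
#> 4           24.1           25.9
#> 5           18.7           19.1
```

Reading the output: the fitted flip angle (10.65°) is the lobar effective
value under the phantom's factor-2 anterior–posterior coil gradient around
the 10° nominal, and T1 recovers the simulated 20 s. The lower lobes
(RLL, LLL) were seeded with the heaviest emphysema (29%, 25% targets —
recovered as 28.9 and 25.1) and correspondingly hold the lowest relative
ventilation shares and the highest defect scores; the five relative shares
sum to exactly 100. The SPECT columns agree with the gas-MRI shares to
within blur-and-Poisson leakage.

For a full cohort (simulate → fit → correct → score → compare, with CSVs,
NIfTI volumes and a manifest):

```r
res <- run_pipeline(pipeline_config(n_subjects = 12, seed = 1), "phantom_run")
print(res$report)
```

A command-line wrapper with the same stages is in
`inst/cli/xelobe.R` (`simulate | fit | score | compare | run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the sum of the
five relative lobar ventilation percentages of a freshly generated phantom
subject (computed from both the decay-corrected gas-MRI volume and the
SPECT count volume), and the median R² of the three-parameter decay fit
over 100 seeded 8-point curves at first-volume SNR 50. Results are written
as JSON to `--out`.

## Further reading

The methods vignette (`vignettes/lobar-ventilation.Rmd`) documents the
signal model and its assumptions, the identifiability analysis, the
correction semantics, every phantom parameter with units and defaults,
the numerical choices, and known limitations.
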