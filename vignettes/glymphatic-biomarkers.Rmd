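---
title: "Glymphatic MRI biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic MRI biomarkers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphr)
```

## The scientific problem

The glymphatic system is the brain's perivascular clearance pathway: CSF
exchanges with interstitial fluid along perivascular spaces and carries
metabolic waste out of the parenchyma. Its failure is implicated in
neurodegeneration, including amyotrophic lateral sclerosis (ALS), where
impaired clearance of misfolded proteins such as TDP-43 may accelerate
motor-neuron loss. Direct tracer studies are invasive, so non-invasive MRI
proxies are used instead. This package implements the analysis chain for
three of them in a case-control setting:

1. **gBOLD–CSF coupling.** The global low-frequency (0.01–0.1 Hz) BOLD
   signal averaged over cortical gray matter (gBOLD) co-fluctuates with
   the CSF inflow signal measured at the edge of the imaging volume.
   The physiological account: a drop in global neural activity reduces
   cerebral blood volume and intracranial pressure, and CSF flows in to
   compensate — so the CSF trace tracks the *negated time derivative* of
   gBOLD. In the lagged cross-correlation between the two signals this
   appears as a positive peak near −4 s and a negative peak near +4 s.
   The scalar marker is the negated correlation at the +4 s lag.
2. **DTI-ALPS.** At the level of the lateral ventricle body, perivascular
   spaces run along the x axis, perpendicular to projection fibers (z)
   and association fibers (y). The index
   `(Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)` therefore rises with
   free diffusion along the perivascular axis; a low index indicates
   restricted perivascular flow.
3. **Choroid plexus volume (CPV) fraction.** The choroid plexus produces
   CSF; its volume as a percentage of total intracranial volume
   (`100·CPV/TIV`) is elevated when clearance is impaired.

Everything upstream of these quantities — registration, smoothing, tensor
fitting, segmentation — is out of scope; the package consumes the signal,
diffusivity and volumetry tables those pipelines produce, and provides a
synthetic generator that emulates their statistical structure so every
stage is testable without imaging data.

## The coupling statistic and its null

`cross_correlate()` computes `r(L) = cor(gBOLD(t + L), CSF(t))` on a
symmetric lag grid with step `tr` (default ±10 s at `tr` = 2 s). Two
conventions are fixed deliberately:

* **Lag sign.** The orientation is the one under which CSF = −d/dt gBOLD
  produces a negative extremum at *positive* lag, matching the observation
  that CSF peaks precede gBOLD peaks.
* **Per-lag renormalization.** Each lag's correlation uses the overlapping
  segment's own means and SDs, the standard estimator when the series
  length shrinks with lag.

`coupling_index()` returns the *signed* negation of `r(+4 s)`, not an
absolute value: group means near zero with SDs around 0.13 are only
possible if subjects with positive `r(+4 s)` receive negative indices, so
the magnitude-only reading of the marker would distort the group
distributions.

The permutation null (`permutation_test()`) reassigns CSF traces across
subjects uniformly at random (identity permitted — at n = 84 its
probability is negligible and the null stays exchangeable), recomputes the
group-mean correlogram per draw, and reports per-lag two-sided p-values
with the add-one estimator `(1 + #{|null| ≥ |obs|})/(n_perm + 1)`, which
cannot return zero. The implementation precomputes the full
subject × subject × lag correlation array once, so 10,000 draws are pure
indexing; this is algebraically identical to recomputing correlations per
draw.

## Temporal preprocessing

Signals pass through discard → detrend → band-pass → z-score
(`prep_signal()`). Defaults mirror standard resting-state practice at
`tr` = 2 s: 10 discarded volumes (magnetization equilibrium), linear
detrend, 0.01–0.1 Hz band. Two filter realizations are provided. The
default is an ideal DFT mask: it is exactly zero-phase (no group delay, so
lag estimates are unbiased) and exactly idempotent — refiltering an
already-filtered trace changes nothing. The alternative
(`method = "butterworth"`) is a 2nd-order Butterworth applied
forward–backward (effective 4th order); it meets the same amplitude
contract (≥ 90% passband retention, ≤ 10% at twice the upper edge) but its
passband droop attenuates band-edge content by a few percent on each
pass, which is why it is not the default. The final z-scoring is cosmetic
for Pearson correlations but fixes the scale of written signal files.

## What the synthetic generator emulates — and what it does not

`generate_marker_table()` draws a 41 ALS / 43 HC cohort with the group
marginals of the study population this package targets: ALPS
1.20 ± 0.16 vs 1.36 ± 0.14, coupling 0.01 ± 0.13 vs 0.16 ± 0.14, CPV
fraction 0.09 ± 0.03% (ALS) vs median 0.06% IQR (0.05, 0.07)% (HC,
log-normal — the reported median/IQR summary indicates right skew), TIV
1598 ± 174 vs 1605 ± 148 ml, ALSFRS-R 33.2 ± 6.0 clipped to the 0–48
scale, log-normal disease duration moment-matched to 20.8 ± 13.3 months,
and a 9/41 bulbar-onset fraction. Design choices worth recording:

* **The ALPS–CPVfraction correlation is imposed on the fraction, not on
  CPV in ml.** A Gaussian copula couples ALPS with the CPV *fraction*
  (default r = −0.537 within ALS), and CPV in ml is derived as
  `fraction/100 × TIV`. Coupling ALPS to CPV in ml instead, with TIV drawn
  independently, would attenuate the realized ALPS–fraction correlation by
  ~5% through TIV noise; parameterizing the fraction directly keeps the
  imposed correlation exact and keeps the identity
  `cpv_fraction = 100·cpv/tiv` true per subject. The implied ALS CPV
  distribution (mean ≈ 1.44 ml) sits slightly above the reported ALS CPV
  median (1.23 ml); the printed group summaries are not mutually
  consistent to that precision, and the fraction — the analyzed marker —
  takes priority.
* **Within-HC markers are independent by default** (`hc_correlation = 0`):
  no within-HC correlation structure is reported, so independence is the
  least-informative default, kept configurable.
* Demographics (age, sex, BMI, education) are generated for table parity
  only; no computation consumes them.

`generate_signal_pair()` reduces CSF-inflow physics to
"CSF ∝ −d/dt gBOLD + noise": gBOLD is narrowband Gaussian noise (spectral
Gaussian bump, SD 0.02 Hz, hard-zeroed outside the passband, so its
spectral mass outside the band is exactly zero on its own grid), and CSF
mixes the unit-variance negated derivative with white noise in variance
proportions `s : 1 − s`. The default peak frequency 1/16 Hz places the
derivative relation's correlogram extrema at ±4 s — a quarter period — on
the 2-s grid. Half-wave rectification (inflow signals are one-sided) is
available but off by default so closed-form sinusoid checks hold exactly.
The generator does **not** simulate motion, physiological noise
regressors, arousal events, sleep structure, scanner drift beyond a linear
trend, or any spatial structure beyond the toy phantom
(`generate_phantom()`), so passing tests demonstrate the estimators'
correctness under the assumed signal model, not robustness to real-world
artifacts.

The marker table and the signal cohort are deliberately two separate
pathways in `run_pipeline()`: the marker table (whose coupling values are
drawn from the published group distributions) feeds the statistics and
diagnostic models, while the signal cohort demonstrates how the coupling
marker is measured from traces and carries the permutation null. Deriving
group-specific marker values from the signal model itself would conflate
the generator's physics with the published group contrasts.

## Statistics

`compare_groups()` gates on Shapiro–Wilk at α = 0.05 in *both* groups
(the normality test itself is a design choice; the criterion is standard
but the test is unnamed in common reporting) and then applies the
pooled-variance Student's t-test or the Mann–Whitney U test, two-sided;
Welch is available by flag. `correlation_matrix()` takes an *explicit*
family of pairs — by default the nine marker–clinical pairs analyzed
within the ALS group — and applies Benjamini–Hochberg step-up across
exactly that family. Published q-values for such families are not always
reproducible from the printed p-values (rounding, or a different family);
standard BH is implemented and no attempt is made to imitate any specific
printed q. `partial_correlation()` residualizes both variables on the
covariate and uses n − 3 reference degrees of freedom.
`icc_reproducibility()` returns both the two-way mixed consistency form
ICC(3,1) and the absolute-agreement form, because the two are easily
conflated in reports; with two measurements per subject they differ only
through the session mean-square term.

## Diagnostic models

`roc_analysis()` wraps pROC (empirical curve, trapezoid AUC ≡ Mann–Whitney
U/(n₁n₂), DeLong 95% CI, Youden-optimal cut-off). The direction flag
orients markers so that "lower ALPS = ALS" and "higher CPV fraction =
ALS" both yield AUC ≥ 0.5; DeLong was chosen as the default CI because it
is the standard analytic interval, with a bootstrap option for parity
checks. `fit_logistic()` is an unregularized IRLS fit (tolerance 1e-8) of
the three markers as linear main effects — no interactions, no
demographics — with complete separation raised as an error rather than
returned as divergent coefficients. `build_nomogram()` uses the
conventional scaling (largest |coefficient × range span| = 100 points) and
maps total points to probability through the exact affine reconstruction
of the linear predictor, so nomogram probabilities agree with model
predictions to machine precision. `calibration_bootstrap()` bins on
deciles of predicted probability (bins under 2 subjects merge with a
neighbor, with a warning) and subtracts bootstrap-estimated optimism
(refit on resample; apparent-minus-test calibration error averaged over
resamples). `decision_curve()` computes net benefit
`TP/N − FP/N·pt/(1−pt)` against the treat-all and treat-none references.

## Numerical choices and degenerate inputs

* Correlogram lags must be multiples of `tr`; a requested index lag absent
  from the grid is an error, never rounded.
* Cross-correlation requires ≥ 32 samples and ≥ 3 overlapping points at
  the extreme lag; filtering requires ≥ 32 samples.
* Ties in ROC scores are handled by the U-statistic convention (half
  credit), and the Youden optimum takes the first threshold on ties.
* Constant series cannot be z-scored or correlated (error); a constant
  covariate in partial correlation falls back to the plain correlation
  with a warning.
* All generators and resampling routines consume explicit integer seeds;
  identical configuration plus seed reproduces outputs bit for bit, and
  derived per-subject seeds are drawn below 2³¹.

## Problem sizes used in the test suite

The suite exercises the full published geometry where it matters — the
84-subject, 240-volume, 10,000-draw permutation analysis runs in seconds
thanks to the precomputed correlation array — and uses reduced Monte-Carlo
sizes elsewhere (e.g. 8-subject, 64-volume cohorts for type-I-error sweeps;
tens to hundreds of replicates for recovery checks), chosen so each
property is tested at 3–4 standard errors of resolution.

## Known limitations

* The signal model is a caricature: one dominant frequency, stationary
  coupling, Gaussian noise. It validates estimator geometry (extremum at
  ±4 s), not physiological realism.
* The diagnostic model has no external validation set; the bootstrap
  optimism correction is the only guard against overfit, as in the
  target study design.
* ICC utilities assume exactly two repeated measurements.
* The phantom pathway is a toy for testing mask extraction, not a
  substitute for spatial preprocessing.
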