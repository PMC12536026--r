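# glymphr

Analysis pipeline for three resting-state MRI proxies of glymphatic
(perivascular clearance) function in ALS case–control cohorts, for
neuroimaging researchers who have already run their spatial preprocessing
and want a tested, reproducible implementation of the downstream
statistics:

* **gBOLD–CSF coupling** — the lagged Pearson cross-correlation between
  the global gray-matter BOLD signal and the CSF inflow signal. Falling
  global activity draws CSF into the imaging volume, so CSF tracks
  −d/dt gBOLD and the cross-correlogram `r(L) = cor(gBOLD(t+L), CSF(t))`
  shows a positive peak at −4 s and a negative peak at +4 s. The subject
  marker is the signed negation of `r(+4 s)`; group-level significance
  comes from a 10,000-draw permutation null that reassigns CSF traces
  across subjects.
* **DTI-ALPS** — the perivascular diffusivity ratio
  `(Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)` from projection- and
  association-fiber ROIs at the lateral ventricle body; lower = more
  restricted perivascular flow.
* **CPV fraction** — choroid plexus volume as a percentage of total
  intracranial volume, `100·CPV/TIV`.

Around these markers the package provides normality-gated group
comparisons (Student's t / Mann–Whitney U after a Shapiro–Wilk gate),
Benjamini–Hochberg-corrected correlation families, partial correlation,
ICC reproducibility, per-marker ROC analysis (DeLong CIs, Youden
cut-offs), a combined logistic nomogram, bootstrap optimism-corrected
calibration, and decision-curve analysis — plus a seeded synthetic cohort
generator (marker tables, derivative-coupled signal pairs, a toy 4-D
phantom) that emulates the statistical structure the analysis assumes, so
the entire pipeline runs and is tested without imaging data.

## Worked example

```r
library(glymphr)

## Synthetic 41 ALS / 43 HC cohort at the published marker distributions
tab <- generate_marker_table(cohort_config(seed = 42))
marker_comparisons(tab)[, c("variable", "test_used", "p")]
#>           variable    test_used        p
#> 1       alps_index    student_t 1.55e-05
#> 2   coupling_index    student_t 2.74e-06
#> 3           cpv_ml mann_whitney 9.84e-07
#> 4           tiv_ml    student_t 9.56e-02
#> 5 cpv_fraction_pct mann_whitney 1.91e-07
```

All three markers separate the groups decisively while TIV does not —
the pattern the markers are designed to show. Within the ALS group the
generator imposes the ALPS–CPVfraction anticorrelation via a Gaussian
copula, and the correlation family recovers it with BH-adjusted q-values:

```r
als <- tab[tab$group == "ALS", ]
correlation_matrix(als, list(c("alps_index", "cpv_fraction_pct"),
                             c("alsfrs_r", "progression_rate")))
#>         var1             var2  n      r        p        q
#> 1 alps_index cpv_fraction_pct 41 -0.504 7.81e-04 7.81e-04
#> 2   alsfrs_r progression_rate 41 -0.646 4.98e-06 9.95e-06

## Per-marker and combined-model discrimination
roc_analysis(tab$coupling_index, tab$group, direction = "less")
#> <roc_result> AUC = 0.787 (95% CI 0.687-0.887), cutoff = 0.03995
#>   (sens 0.732, spec 0.791), higher-is-positive: FALSE
model <- fit_logistic(tab[c("coupling_index", "alps_index",
                            "cpv_fraction_pct")], tab$group)
roc_analysis(model$fitted, tab$group, direction = "greater")
#> <roc_result> AUC = 0.909 (95% CI 0.845-0.973), cutoff = 0.5578
#>   (sens 0.829, spec 0.930), higher-is-positive: TRUE
```

The coupling marker alone reaches AUC ≈ 0.79; combining the three markers
lifts the model to AUC ≈ 0.91 on this draw. The signal pathway shows where
the coupling marker comes from — a cohort of derivative-coupled traces
puts the group-mean correlogram extremum exactly at +4 s:

```r
pairs <- generate_signal_cohort(84, signal_config(coupling_strength = 0.9,
                                                  seed = 1))
cp <- cohort_coupling(pairs)   # discard 10, detrend, 0.01-0.1 Hz, correlate
gm <- group_mean_correlogram(cp$correlograms)
pt <- permutation_test(cp$prepped, n_perm = 10000, seed = 2)
gm$lag[which.min(gm$r)]        # 4  (seconds)
pt$p[pt$lags == 4]             # 1e-04  (add-one permutation p-value)
```

`run_pipeline(run_config(seed = 7), out_dir = "results/run7")` executes
every stage end to end and writes the subject table, comparison and
correlation CSVs, per-subject coupling results, the group correlogram JSON
with its permutation band, ROC summaries, the nomogram/model JSON, the
calibration table and the decision curve. `scripts/run_cohort.R` wraps
this as a shell command.

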