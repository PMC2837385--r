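# bloodvar

Dissecting technical and biological sources of variation in
population-scale whole-blood gene expression studies.

Whole blood is the tissue of choice for molecular epidemiology: it is easy
to collect at scale and mirrors exposures (smoking, medication, hormone
therapy) and inter-individual state (BMI, fasting, age). But the
expression changes involved are subtle, and in a cohort processed over
months the technical layer — array manufacturing lots, RNA extraction
batches, the time a sample waited before freezing — can dwarf the biology.
`bloodvar` implements the full analysis cascade such a study needs, for
analysts working with probe-level microarray matrices accompanied by
per-cell signal-to-noise (S/N) ratios and quality flags:

1. **QC / preprocessing** (`qc_preprocess()`): mask cells with flag
   > 8191, resolve technical replicates (keep the array with the most
   probes at S/N > 3), drop arrays with fewer than 40% of probes at
   S/N ≥ 3 and probes detected (S/N > 3) in fewer than 50% of samples,
   then log2-transform, quantile-normalize (missing-aware) and impute by
   inverse-distance-weighted 10-nearest-neighbour probes.
2. **Technical screen** (`screen_variables()`): global analysis of
   covariance across the whole matrix. For nested per-probe OLS models the
   statistic is the extra-sum-of-squares ratio
   `T = Σ_g (RSS_g^red − RSS_g^full) / Σ_g RSS_g^full`,
   calibrated by Freedman–Lane permutation of reduced-model residuals;
   technical covariates passing the multivariate screen at permuted
   p < 0.001 move forward.
3. **Variance decomposition** (`eigen_r2()`): the eigenR2 statistic, a
   high-dimensional R²: regress each eigengene (right-singular vector of
   the probe-centered matrix) on a variable set and average the
   per-eigengene R² with eigenvalue-share weights.
4. **Per-probe model selection** (`build_association_matrix()`): for every
   probe, a linear mixed model with crossed random intercepts for batch
   factors, chosen by forward–backward search on BIC
   (`−2ℓ̂_ML + k·log n`) over a 10-variable candidate pool (biological and
   exposure covariates, their declared interaction, and the screened
   technical variables).
5. **Core-probe selection** (`global_test_scores()`,
   `select_core_weighted()`): global-test scoring of each variable's
   selected probe set. Per probe, `Q_i = (x_i · r)²` with outcome and
   probes residualized on the adjustment design; permutation moments give
   z-scores, and the core set maximizes the utility
   `U(t) = 2·S(t)·(1 − FDR(t)) − 1·S(t)·FDR(t)` over all |z| cutpoints
   (Benjamini–Hochberg FDR).
6. **Gene-set enrichment** (`enrichment_analysis()`): curated GMT sets
   tested with the global test, BH-adjusted across sets, with a
   competitive comparative p-value — the fraction of random same-size
   probe sets with a larger standardized set statistic.

A synthetic cohort generator (`simulate_cohort()`) reproduces the variance
structure this pipeline assumes — crossed lot/extraction-date random
effects, a degradation slope on days-to-freezing, covariate-linked
differential signal at realistic prevalences, S/N-based detection,
flag-driven missingness, technical replicates — and records the ground
truth, so every stage is testable without any download.

## Worked example

```r
library(bloodvar)

cfg <- cohort_config(n_samples = 120, n_probes = 1000, seed = 42)
cfg <- calibrate_variance_fractions(cfg, technical = 0.465, biological = 0.081)
sim <- simulate_cohort(cfg)

qc <- qc_preprocess(sim$expr, sim$annotations)
print(qc$report)
#> qc_report: arrays 135 -> 120, probes 1000 -> 470
#>   excluded arrays: S0018 (technical replicate with fewer detected probes), ...
#>   excluded probes: 530
#>   replicate resolutions: 15 subjects

scr <- screen_variables(qc$expr, qc$annotations,
                        c(variables_with_role(qc$annotations, "technical-random"),
                          variables_with_role(qc$annotations, "technical-fixed")),
                        n_perm = 1000, seed = 1)
print(scr)
#> technical variable screen (multivariate alpha = 0.001):
#>         variable univariate_p multivariate_p   role passed
#>              lot  0.000999001    0.000999001 random   TRUE
#>  extraction_date  0.000999001    0.000999001 random   TRUE
#>      freeze_days  0.000999001    0.000999001  fixed   TRUE
#>      tech_decoy1  0.840159840    0.573426573  fixed  FALSE
#>      ...

eigen_r2(qc$expr, qc$annotations, names(scr$passed))
#> eigenR2 = 0.498 (unadjusted R2, 119 eigengenes) for: lot, extraction_date, freeze_days

pool  <- candidate_pool(qc$annotations, screen = scr)
assoc <- build_association_matrix(qc$expr, pool, qc$annotations)
print(assoc)
#> association_result: 470 probes, 3.72 variables/probe (SD 1.25)
#>       age_class         fasting       bmi_class         smoking              ht
#>              18             115              85              72             142
#>             med          ht:med     freeze_days             lot extraction_date
#>             231               7             314             419             346

sc <- global_test_scores(qc$expr, qc$annotations, "smoking",
        probe_set = rownames(assoc$matrix)[assoc$matrix[, "smoking"] == 1],
        adjust = "lot", n_perm = 1000, seed = 2)
select_core_weighted(sc)
#> core_selection 'smoking': 59 probes at |z| >= 2.5 (FDR 0.0151)
```

Reading the output: 15 replicate arrays and 530 undetected probes fall in
QC; the screen isolates exactly the three technical variables that truly
drive expression (the five decoys fail the multivariate test); eigenR2
puts the technical share of variation near the designed 46.5%; the
mixed-model search associates each probe with 3.7 variables on average,
dominated by array lot; and the weighted z-score rule trims the 72
smoking-associated probes to a 59-probe core at an estimated FDR of 1.5%.

The same stages run from the shell via
`Rscript inst/scripts/bloodvar.R simulate|qc|run ...`, reading and writing
tab-delimited matrices, role-annotated CSVs and GMT gene sets
(`run_pipeline()` is the programmatic equivalent).

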