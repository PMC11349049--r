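# cd8basket

Translational and statistical analyses for a CD8-stratified immunotherapy
basket trial, packaged as tested, reusable R functions. The setting: patients
with advanced solid tumors are stratified at enrolment by their tumoral CD8
T-cell percentage (CD8-low < 15%, CD8-high ≥ 15%), treated with combination
checkpoint blockade, and followed with serial biopsies and multi-omic
profiling. The package implements the trial's endpoint statistics and every
downstream biomarker analysis, plus seeded synthetic-data generators with
planted ground truth so the whole pipeline is recovery-testable without
patient data.

## What it computes

**Clinical endpoints** (`summarize_endpoints()`, `beta_binomial_interval()`,
`conversion_interval()`, `fit_logistic_wald()`, `fisher_exact_2x2()`).
Disease control (CR/PR or SD ≥ 24 weeks), objective response (CR/PR), and
CD8 conversion (any on-treatment biopsy reaching ≥ 15%). Rate uncertainty is
Bayesian: for a rate with *s* successes in *n* patients and a Beta(α₀, β₀)
prior, the 95% credible interval is the pair of equal-tailed quantiles of
the Beta(α₀ + s, β₀ + n − s) posterior. DCR/ORR use the trial's
Beta(0.4, 1.6) prior; the conversion interval is computed under both
readings of "no prior" (improper Beta(0, 0) and uniform Beta(1, 1)).

**Layer-aware differential comparison** (`differential_features()`,
`layer_rule()`). One equal-variance Student *t* per feature, with a
significance call that is the conjunction of a raw p gate and an effect
gate, preset per assay layer: RNA (p < 0.05, |log₂FC| > 1), serum
proteomics NPX (p < 0.05, |log₂FC| > 0.75), CyTOF (p < 0.01), X50 flow
(p < 0.05, |Δmean| > 20 points), mIF (p < 0.05, |Δmean| > 5 points).
Supporting steps: quantile normalization, within-subject baseline
subtraction, mean-of-z-score signature scoring, hypergeometric
over-representation.

**mIF phenotyping** (`kmeans_threshold()`, `mif_cell_calls()`,
`phenotype_cells()`, `percent_of_parent()`). Per image and marker, a
background threshold is the mean of the two largest of three k-means
centers fit to the pooled pixel intensities of all segmented cells; the
1-D k-means is solved *exactly* by dynamic programming, so thresholds are
deterministic. A cell is positive when > 50% of its pixels exceed the
threshold; populations are defined hierarchically and reported as
percent-of-parent per ROI, averaged per image.

**Principal-curve pseudotime** (`fit_principal_curve()`,
`trajectory_tests()`). Hastie–Stuetzle alternation of smoothing-spline
coordinate fits and orthogonal re-projection on a cells × components
embedding; no start cell required. Genes are tested with a Gaussian GLM of
z-scored expression on pseudotime with vendor as covariate
(group/timepoint modes add the factor and its pseudotime interaction),
gated at Bonferroni-adjusted p ≤ 0.10 with coefficient cutoffs ±1
(trajectory) or ±0.25 (group/timepoint).

**TCR repertoire** (`chao1()`, `shared_clones()`, `blood_tumor_overlap()`):
Chao1 richness S_obs + f₁²/(2 f₂) with the bias-corrected fallback at
f₂ = 0, cross-patient public-clone detection, blood–tumor overlap.

**ctDNA** (`ctdna_positive()`, `classify_decrease()`,
`baseline_adjusted_comparison()`): positivity at ≥ 2 of 16 SNVs detected,
molecular response at a ≥ 50% decrease from baseline, and response-group
comparison of log₁₀ baseline-adjusted on-treatment concentrations.

## Worked example

```r
library(cd8basket)

sim <- simulate_cohort(seed = 7)          # 72 CD8-low + 7 CD8-high patients
res <- summarize_endpoints(sim$patients)
print(res$cd8_low$dcr)
#> 16/72 = 22.2% (95% credible interval: 13.5-32.2)
print(res$conversion$intervals$improper_zero)
#> 14/41 = 34.1% (95% credible interval: 20.6-49.1)
```

16 of the 72 simulated CD8-low patients achieved disease control, giving a
posterior Beta(16.4, 57.6) under the Beta(0.4, 1.6) prior and the printed
22.2% (13.5–32.2) rate; 14 of 41 biopsied patients converted to CD8-high,
with the no-prior (improper) interval shown.

```r
om <- simulate_omics(n_features = 172, n_per_group = 12, frac_true = 0.1,
                     effect = 1.5, noise_sd = 0.5, layer = "NPX", seed = 7)
de <- differential_features(om$fm, om$meta$group)   # NPX preset rule
head(de[, c("feature", "effect", "p", "significant")], 3)
#>    feature   effect            p significant
#> 67   f0067 1.705769 1.199275e-09        TRUE
#> 34   f0034 1.530793 4.795416e-09        TRUE
#> 86   f0086 1.554387 6.900685e-09        TRUE
sum(de$significant)
#> [1] 17
```

The NPX rule (p < 0.05 and |log₂FC| > 0.75) flags 17 cytokines — exactly
the 17 planted by the generator, whose identities are in `om$truth$planted`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the package's design decisions.
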