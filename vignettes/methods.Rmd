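---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd8basket)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made.

## Clinical endpoints

A patient is an **objective responder** when the best overall response (BOR)
is CR or PR, and achieves **disease control** when the BOR is CR, PR, or SD
sustained at least `sd_min_duration_weeks` (default 24 weeks — the endpoint
definition; a 6-month reading also circulates for this endpoint family, and
the threshold is a config field precisely so either can be used). BOR `NE`
counts as non-response, keeping the intent-to-treat denominator. **CD8
conversion** is defined only for CD8-low patients: the maximum on-treatment
tumoral CD8 percentage reaches the 15% cutoff. Patients without an
on-treatment biopsy are `NOT_EVALUABLE` and excluded from the conversion
denominator.

Rate uncertainty is Bayesian. With $s$ successes in $n$ patients and a
$\mathrm{Beta}(\alpha_0,\beta_0)$ prior, the posterior is
$\mathrm{Beta}(\alpha_0+s,\ \beta_0+n-s)$ and the reported interval is the
equal-tailed pair of posterior quantiles (`qbeta`, which inverts the
regularized incomplete beta function far below the 1e-9 tolerance we
require). DCR and ORR use $\mathrm{Beta}(0.4, 1.6)$ — an informative prior
centered at 20%, a plausible response rate for checkpoint blockade in
unselected solid tumors. Percentages are displayed to one decimal with
half-up rounding, matching the convention of clinical reports (base R's
`round()` rounds half to even, which would disagree on boundary cases).

**The "no prior" conversion interval.** Two readings are defensible:
the improper $\mathrm{Beta}(0,0)$ (posterior $\mathrm{Beta}(s, n-s)$ —
literally zero pseudo-counts) and the uniform $\mathrm{Beta}(1,1)$.
`conversion_interval_both()` reports both. For 14 converters of 39
evaluable, the improper reading gives (21.8, 51.4)% and the uniform
(22.7, 51.7)%; the improper reading is the package default. It is
undefined at $s \in \{0, n\}$, where the function errors with advice to
switch to the uniform prior rather than silently substituting.

Logistic association (`fit_logistic_wald`) is a binomial GLM fit by IRLS
with an intercept; p-values are two-sided Wald tests on the normal
reference (not $t$), consistent with standard trial software. Complete or
quasi-complete separation — boundary fitted probabilities or exploding
standard errors — is flagged as non-converged with a warning, never
returned silently.

## Layer-aware differential comparison

Every differential comparison in the pipeline is the same primitive: an
equal-variance two-sample Student $t$ per feature, with a significance call
that is the *conjunction* of a raw-p gate and an effect gate. The presets:

| layer | p gate | effect metric | effect gate |
|---|---|---|---|
| RNA (TPM, log2) | 0.05 | log2 fold change | 1 |
| NPX proteomics | 0.05 | log2 fold change | 0.75 |
| CyTOF % of parent | 0.01 | mean difference | none |
| X50 flow % of parent | 0.05 | mean difference | 20 points |
| mIF % of parent | 0.05 | mean difference | 5 points |

Choices worth noting:

* "Student's t test" is taken literally as the pooled equal-variance test;
  Welch is deliberately not the default. Zero pooled variance makes the
  statistic undefined; such features are flagged `testable = FALSE` rather
  than erroring, since all-zero features are routine in omics matrices.
* No multiple-testing correction is applied inside
  `differential_features()`: the rule is raw p plus an effect gate. Users
  who want BH/Bonferroni can adjust the returned `p` column.
* log2 fold change for TPM is the difference of group means of
  $\log_2(\mathrm{TPM}+1)$. The pseudocount 1 makes the transform well
  defined at zero and is the dominant convention.
* Quantile normalization (via `limma::normalizeQuantiles`) maps every
  sample to the across-sample mean of order statistics; ties share the
  mean of the reference values they span. The operation is idempotent,
  which the tests assert.
* Signature scores z-score each member gene **across all samples in the
  matrix** and average the z-scores per sample. The alternative axis
  (z-score across genes) does not yield a per-sample signature and was
  rejected.

## mIF phenotyping

The thresholding algorithm is the package's most bespoke component. Per
image and marker, the pixel intensities of all segmented cells (mask
interiors only — background pixels never enter) are pooled and clustered
into $k = 3$ groups; the background threshold is the mean of the two
largest centers. Rather than seeded Lloyd iterations, the 1-D problem is
solved **exactly** by dynamic programming over the sorted values with
divide-and-conquer optimization ($O(kn\log n)$): optimal clusters of a 1-D
sample are contiguous runs, the per-run SSE cost is concave-Monge, and the
optimal split index is monotone. This makes thresholds deterministic —
there is no initialization or seed to report — and the test suite verifies
the DP solution never has higher within-cluster SSE than 50 Lloyd restarts.
Equal-SSE ties are broken toward the smallest boundary index.

A cell is positive when **strictly more than half** of its pixels
**strictly exceed** the threshold (both inequalities strict; a cell with
exactly half its pixels above, or all pixels equal to the threshold, is
negative). Populations are defined by required-positive and
required-negative markers plus a parent population; membership requires
parent membership, so child counts can never exceed parent counts.
Percent-of-parent is computed per ROI and averaged **unweighted** across
the ROIs of an image; ROIs whose parent population is empty are excluded
from the average and recorded as not evaluable.

Degenerate inputs: fewer than three distinct pixel values is an error
naming the image and marker — a silent degenerate threshold would poison
every downstream call. Each threshold carries a `separation` QC score (gap
between the two largest centers over the summed sds of those two clusters);
values below about 2 arise when the marker distribution is effectively
unimodal, the regime where positivity calls approach chance and results
should not be trusted.

## Principal-curve pseudotime and trajectory GLMs

`fit_principal_curve()` implements the Hastie–Stuetzle alternation:
initialize pseudotime by projection onto the first principal component;
then repeatedly (i) smooth each embedding coordinate against pseudotime
with a cubic smoothing spline whose penalty is chosen by generalized
cross-validation, and (ii) re-project every cell onto the discretized curve
(200 points by default; arc length by cumulative chord length). Iteration
stops when the relative decrease in total squared orthogonal distance falls
below `tol = 1e-4`, at `max_iter = 1000`, or when an iteration would
*increase* the distance — GCV re-selection can jitter at the fixed point,
and in that case the previous state is kept, so the recorded distance trace
is non-increasing by construction. Pseudotime is min-max scaled to [0, 1].
Orientation is arbitrary (the curve has no intrinsic direction); passing
`orient_by =` a score expected to be high early (e.g. a naive-marker
signature) fixes the sign, and the flip is recorded.

The initialization matters: a principal curve found from a PC1 ordering
assumes the trajectory's longitudinal axis dominates the embedding
variance. Trajectories curled so tightly that a transverse direction
carries more variance can converge to a parametrization along the wrong
axis; this is a known property of the algorithm, not of this
implementation.

`trajectory_tests()` fits, per gene, an ordinary-least-squares Gaussian GLM
of (by default z-scored) expression on pseudotime plus covariates (vendor
by default, absorbing batch offsets). In GROUP/TIMEPOINT mode the model
adds the two-level factor and its pseudotime interaction, and the
**interaction** coefficient is tested: the question is whether a gene's
trajectory association differs by response or timepoint, which a main
effect alone cannot express. A main-effect-only mode
(`interaction = FALSE`) is provided since the wording of such analyses
supports either. Significance requires Bonferroni-adjusted
$p \le 0.10$ (adjusted across the genes in the call) **and** a coefficient
magnitude above ±1 (trajectory mode) or ±0.25 (group/timepoint mode).
The cutoffs live on the z-scored-gene scale, which is why scaling is the
default; recovery tests that compare against planted raw coefficients use
`scale_genes = FALSE`, exploiting the model's equivariance.

Density trends along pseudotime use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth on a 256-point grid over [0, 1], with boundary
reflection at 0 and 1 so each curve integrates to one and a uniform
distribution stays flat. A point-mass stratum (zero bandwidth) falls back
to a 0.001 bandwidth; strata under 20 cells are suppressed with a warning.

## TCR repertoire and ctDNA

Chao1 is $S_{obs} + f_1^2/(2 f_2)$ with the bias-corrected fallback
$S_{obs} + f_1(f_1-1)/2$ when $f_2 = 0$; the variant used is recorded in
every result. Clone identity is exact CDR3 amino-acid identity within
chain — nucleotide-level identity would be stricter and V/J-aware identity
looser; amino-acid identity is the common choice for cross-patient
("public") clone analysis. Duplicate records are collapsed by summing
counts before any estimation.

ctDNA positivity is ≥ 2 of 16 patient-specific SNVs detected; molecular
response is an on-treatment concentration at most half of baseline
(boundary inclusive). A zero baseline makes the ratio undefined: the call
is not evaluable rather than forced. The group comparison uses per-patient
$\Delta = \log_{10}(\mathrm{C2D1}) - \log_{10}(\mathrm{BL})$, which is
invariant to the concentration unit; the logistic association uses
$\log_{10}$ baseline with a half-minimum offset only when zeros are
present.

## Synthetic data: what it does and does not show

Each generator is a pure function of its configuration and seed (one RNG
scope per call; the caller's RNG state is untouched) and returns a `truth`
list sufficient to score recovery. The defaults encode the study's own
conditions: 72 CD8-low and 7 CD8-high patients, ~54% biopsy rate, a
conversion rate near 36% among biopsied patients, bimodal mIF channels with
5-sd mode separation and 30% positive fraction, 2-vendor batch offsets on
trajectory genes, and a 16-SNV ctDNA panel.

Distributional choices are deliberately simple: Gaussian noise on the
working scale, uniform latent pseudotime, Fisher log-series clone
abundances, log-normal ctDNA baselines. The generators therefore validate
the *statistics* — that planted effects of stated size are recovered at
stated power, that null data yield nominal error rates, that thresholds
land between planted modes — and not the *biology*: real omics layers have
correlated features, heavier tails, and structured batch effects; real
pixel distributions are not two Gaussians; real repertoires are not
log-series. Passing tests show the machinery is correct under its stated
assumptions, not that those assumptions hold in any given dataset.

Problem sizes used in the test suite (chosen to make the Monte-Carlo
margins comfortable): 50 synthetic images for mIF recovery; 10 seeds of
2,000 cells for S-curve pseudotime; 100 seeds for GLM coefficient coverage
and 200 replicates for familywise error; 10,000 null features for t-gate
calibration and 20 replicates of the 1,000-feature planted design for
sensitivity; $10^6$ posterior draws for the beta-quantile oracle.

## Interfaces

The package is driven from R: the exported functions are the API, the
generators produce any input layer on demand, and `write_simulation()`
serializes tables to TSV/JSON for exchange with other tools.
`scripts/acceptance.R` is the one command-line entry point, recomputing the
endpoint credible intervals from cohort counts and writing them as JSON.

## Known limitations

* Survival endpoints (Kaplan–Meier OS/PFS) are out of scope; no
  patient-level time-to-event data flow through the package.
* Cell segmentation, spectral unmixing, and embedding construction
  (PCA/Harmony/UMAP) are upstream: the mIF module consumes segmented pixel
  tables and the trajectory module consumes any cells × components matrix.
* The principal curve assumes a single, non-branching trajectory.
* The equal-variance t is anti-conservative under strong
  heteroscedasticity; `student_t_two_sample` is the deliberate default for
  fidelity to the analysis it reimplements, not a general recommendation.
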