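# vcfaccuracy

Diagnostic-accuracy validation of a patient-level vertebral compression
fracture (VCF) detector against a dual-reader, adjudicated, Genant-graded
radiologist reference standard.

Opportunistic screening reads VCFs off CT scans of the chest or
abdomen/pelvis that were ordered for unrelated reasons.  A machine-learning
detector that flags such scans returns one of *positive*, *negative* or
*non-evaluable* per patient; validating it requires a reference standard
built from paired neuroradiologist readings (vertebral level plus Genant
grade 1–3 per fracture, disagreements resolved by a senior reader) and a
statistical analysis that respects the quirks of that design: exact
binomial intervals for proportions, log-scale intervals for likelihood
ratios, non-evaluable scans excluded from the primary tables but counted
against sensitivity in a secondary analysis, and inter-rater reliability
estimated from an unbalanced two-of-three-raters design.

This package implements that entire analysis as reusable, tested functions,
plus a synthetic cohort generator so the full pipeline runs with no
external data.  It is aimed at biostatisticians validating binary
patient-level imaging classifiers against adjudicated reader panels.

## The statistics at the core

For a 2×2 table (TP, FN, FP, TN) of reference status against detector
result on the evaluable scans:

* **Sensitivity, specificity, PPV, NPV** with exact Clopper–Pearson
  intervals obtained by inverting the binomial tails
  (`qbeta(α/2, k, n−k+1)` / `qbeta(1−α/2, k+1, n−k)`).
* **Likelihood ratios** LR+ = sens/(1−spec), LR− = (1−sens)/spec, with CIs
  symmetric on the log scale from the delta-method variance
  `var(log LR+) = 1/TP − 1/(TP+FN) + 1/FP − 1/(FP+TN)`.
* **Inclusive sensitivity**: under equal prevalence among non-evaluable
  scans, sensitivity scaled by the evaluable fraction,
  `sens × n_evaluable / n_total`.
* **Sample size for LR precision**: the smallest n such that the expected
  lower log-scale confidence bound of LR+ clears a prespecified value.
* **Inter-rater ICC** σ²_subject/(σ²_subject + σ²_resid) from a REML
  variance-components fit of `rating ~ rater (fixed) + patient (random)`,
  with 95% bias-corrected accelerated (BCa) bootstrap intervals resampling
  patients as blocks.

The reference standard is dichotomized at four thresholds: any VCF
(grade ≥ 1), moderate/severe (grade ≥ 2), severe (grade 3), and two or
more fractures.

## Worked example

`load_paper_fixture()` reconstructs, by deterministic constraint
satisfaction, a 1200-patient dataset consistent with every published margin
of the validation study at once (the four 2×2 tables, the grade and
multiplicity distributions, and all per-vertebral-level counts):

```r
library(vcfaccuracy)
fix <- load_paper_fixture()
t_any <- build_table(fix$reference, fix$index, "any")
t_any
#> 2x2 table: Mild, moderate, or severe versus no VCF
#>           algorithm
#> reference  positive negative
#>   positive      149       78
#>   negative       82      778
#> (113 non-evaluable patient(s) excluded)

accuracy_summary(t_any)[1:2, c("statistic", "point", "ci_low", "ci_high")]
#>     statistic     point    ci_low   ci_high
#> 1 sensitivity 0.6563877 0.5906690 0.7179604
#> 2 specificity 0.9046512 0.8830303 0.9234479

likelihood_ratios(t_any)[1, c("statistic", "point", "ci_low", "ci_high")]
#>   statistic    point   ci_low  ci_high
#> 1    lr_pos 6.884066 5.489564 8.63281

inclusive_sensitivity(t_any, n_total = 1200, n_evaluable = 1087)
#> 149/251 = 0.59 (95% CI 0.53-0.65, clopper_pearson_augmented)
```

A detector positive therefore multiplies the odds of any VCF by 6.9; the
sensitivity of 0.66 on evaluable scans drops to 0.59 once the 113
non-evaluable scans are counted against it.

The synthetic workflow runs the same analysis end to end with no external
data — each script prints what it found and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort, readings, detector, demographics
Rscript analysis/02_reference_standard.R  # dual-reader adjudication
Rscript analysis/03_diagnostic_accuracy.R # 2x2 tables, CIs, LRs, sample size
Rscript analysis/04_reliability.R         # ICC presence/severity/count with BCa CIs
Rscript analysis/05_report.R              # full deterministic study report
```

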