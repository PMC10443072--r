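---
title: "Validating a patient-level VCF detector: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a patient-level VCF detector: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfaccuracy)
```

This vignette is the package's account of its statistical content: the
models behind each function, the parameters that matter and their defaults,
what the synthetic generator does and does not emulate, the numerical
choices, and the places where the analysis design was genuinely open and a
decision had to be made.

## The validation design

A patient-level binary detector for vertebral compression fractures (VCFs)
is scored against a reference standard built from radiologist readings.
Each patient's CT scan is read independently by two neuroradiologists drawn
from a pool of three; a reading is a set of (vertebral level, Genant grade)
pairs over the 17 levels T1–T12, L1–L5, with grades 1 (mild), 2 (moderate),
3 (severe).  Any disagreement in presence, location, or grade sends the
scan to a senior reader whose reading becomes the final diagnosis
(`build_reference()`).  The detector returns `positive`, `negative` or
`non_evaluable` per patient and does not localize fractures.

Two structural consequences drive the analysis:

* **Non-evaluable scans** are excluded from the primary 2×2 tables
  (`build_table()` tallies them separately) but are counted against
  sensitivity in a secondary analysis (`inclusive_sensitivity()`).
* **The vertebral-level table** (`vertebral_sensitivity_table()`) crosses a
  vertebral-level reference with a patient-level detector result.  It is a
  descriptive cross-level construct — "among patients fractured at L1, how
  often did the patient-level detector fire" — not a per-level accuracy
  claim, because the detector cannot attribute its positive to a level.
  A multi-fracture patient intentionally contributes to every fractured
  level.

## Interval estimation

**Proportions.** All proportion CIs are exact Clopper–Pearson intervals,
computed by the beta-quantile inversion of the binomial tails.  Exactness
matters here because several cells are small (vertebral levels with 2–8
reference-positive patients) and the intervals are reported at degenerate
boundaries (`k = 0` gives a lower bound of exactly 0, `k = n` an upper
bound of exactly 1).  The test suite checks the implementation two
independent ways: against `binom.test()` and against a brute-force
bisection of the `pbinom` tail sums (agreement to 1e-10 over all
`n <= 30`), and verifies the method's conservatism by simulation
(empirical coverage at least nominal at p = 0.05, 0.5, 0.9).

**Likelihood ratios.** LR+ and LR− are ratios of two independent binomial
proportions, so the interval is built on the log scale with the
delta-method variance, e.g. `var(log LR+) = 1/TP − 1/(TP+FN) + 1/FP −
1/(FP+TN)`, and exponentiated — the interval a log-link binomial regression
of test positivity on reference status reproduces.  Published analyses
sometimes label this "log-linear regression", a phrase that covers several
software-specific variants; intervals printed elsewhere can therefore
differ slightly from this formula, and can even be asymmetric around the
point estimate on the log scale, which no two-group log-method reproduces.
For that reason the package's LR intervals are validated by their
properties (log-scale symmetry, algebraic identities
`LR+·(1−spec) = sens`, `DOR = LR+/LR−`) rather than by matching any
particular printed interval.  Zero cells: in strict mode an error; by
default 0.5 is added to all four cells *for the ratio estimates only*
(recorded in the output; exact CIs are never corrected).

**Inclusive sensitivity.** With attrition (non-evaluable scans) and the
assumption that reference-positivity has the same prevalence among
evaluable and non-evaluable scans, the point estimate is multiplicative:
`sens × n_evaluable/n_total`.  That assumption is a modelling choice, not
a fact of the design — detectors may fail preferentially on degraded scans
of sicker patients.  For the interval, the expected number of
reference-positives among the non-evaluable scans is imputed into the
denominator (rounded) with zero added to the numerator, and a
Clopper–Pearson interval is taken on the augmented counts; this is
conservative in the same direction as the point estimate.

**Sample size.** `sample_size_for_lr()` finds the smallest n whose expected
log-scale lower bound for LR+ clears a prespecified exclusion value, using
the delta-method variance at the expected cell counts.  The closed form
`n = c·z²/log(LR+/exclude)²` is verified against a grid-search oracle in
the tests.  The prevalence defaults to 0.15, a mid-range figure for VCF
prevalence in over-50 imaging populations; it is exposed as an argument
because designs at other prevalences scale `c` directly.

## The reliability model

Initial (pre-adjudication) ratings are analysed as a linear mixed model:

$$y_{ij} = \mu + r_j + b_i + e_{ij}, \qquad
b_i \sim N(0, \sigma^2_b),\; e_{ij} \sim N(0, \sigma^2_e),$$

with rater $j$ a *fixed* effect and patient $i$ a random intercept; the
ICC is $\sigma^2_b/(\sigma^2_b+\sigma^2_e)$.  Three outcomes are analysed,
each treated as continuous even when binary or ordinal: presence (0/1),
severity of the most severe VCF (0–3), and fracture count.  Treating them
as continuous is deliberate — the variance-ratio ICC is then directly
interpretable and comparable across the three outcomes — at the cost of
the usual caveats about linear models for bounded outcomes.

Rater enters as a fixed effect rather than a second variance component: a
pool of three raters is far too small to estimate a rater variance stably,
and the target estimand uses only subject and residual variance.  A
three-rater random effect would also be weakly identified in the
two-of-three design, where rater and patient are partially confounded.

**Fitting.** `fit_variance_components()` is a REML fit written for this
block structure: ratings are independent across patients, so the marginal
covariance is block diagonal and the REML criterion profiles to a
one-dimensional search over $\theta = \sigma^2_b/\sigma^2_e$.  All data
enter through a handful of per-patient sufficient statistics, making one
likelihood evaluation O(1) after an O(n) reduction — fast enough to refit
inside bootstrap and jackknife loops (hundreds of thousands of fits in the
test suite).  The numerical choices:

* outcomes are centered before the quadratic forms are accumulated, so the
  ICC is invariant to location shifts at machine precision;
* the search runs over $\log\theta \in [-30, 15]$ with Brent's method,
  then polishes interior optima with finite-difference Newton steps
  (Brent alone stops near $\sqrt{\varepsilon}$, which is visible when the
  estimate is compared to an ANOVA oracle at 1e-8);
* $\theta$ at the lower boundary is truncation of a negative subject
  variance to 0 (ICC 0); the upper boundary means zero residual variance
  (e.g. raters in perfect agreement) and returns ICC 1 with a
  `degenerate` flag, as does a constant outcome;
* raters absent from a resample drop out of the fixed-effects design
  automatically.

On balanced complete designs the estimate coincides with the classical
two-way consistency ICC, `(MSR − MSE)/(MSR + (k−1)·MSE)`, which the tests
verify against `aov()` to 1e-8; on the 2-of-3 design it matches
`lme4::lmer` to 1e-6.

**BCa bootstrap.** `bca_ci()` resamples *patients* (both ratings travel as
a block; rater identities are never resampled), with bias-correction $z_0$
from the fraction of bootstrap statistics below the point estimate and
acceleration from the jackknife-over-patients skewness formula.  Sampled
patients appearing twice are treated as distinct blocks.  Statistics may
fail on individual resamples (degenerate resampled designs); failures are
dropped up to 5%, beyond which the interval aborts with diagnostics.  The
default 1000 resamples matches the analysis design; coverage is verified
in the tests by a scaled-down simulation (200 replicates of n = 300
patients at true ICC 0.70 with 500 resamples, requiring ≥ 88% empirical
coverage of the nominal 95% interval — the 88% floor is the Monte-Carlo
tolerance of 200 replicates, not a claim that BCa undercovers by 7
points).

## The synthetic cohort generator

`generate_cohort()` simulates the full data-generating process the
analysis assumes.  Its defaults (`default_config()`) are the study
conditions: 1200 patients, VCF prevalence 227/1087 among evaluable scans,
highest-grade mix 90:81:56, multi-fracture probability 115/227,
non-evaluable rate 113/1200, grade-specific detector sensitivities 42/90,
60/81, 47/56, false-positive rate 82/860, fracture levels weighted by the
observed per-level distribution (concentrated at T8 and the thoracolumbar
junction T11–L2), and demographics (54% women among evaluable, ages
spread over the five bins between 50 and 102, regions roughly 80/14/6%
chest / abdomen-pelvis / both).  Prior-documented-VCF flags are enriched
among fractured patients (66/227 vs 25/860), mirroring a design that
deliberately over-samples scans with previously verified fractures.

Choices the data could not dictate, fixed once:

* **Fracture counts.** Multi-fracture patients draw 1 or
  2 + Geometric(0.55) fractures (truncated at 17); the geometric tail is
  the simplest monotone count model and its default gives a mean near 2.8
  fractures per multi-fracture patient, consistent with the per-level
  totals implying roughly three fractures per such patient.
* **Reader noise.** For each true fracture a reader first detects it
  (Bernoulli, `rater_presence_agreement`, default 0.85), then reports a
  grade from row g of a 4×4 confusion matrix; spurious findings on intact
  levels come from row 0 (default ≈ 0.35% per level per reader).  The
  senior reader uses a much milder profile (0.97 detection, near-identity
  confusion), and `perfect_senior = TRUE` makes the adjudicated reference
  equal the truth exactly — the configuration used for end-to-end identity
  tests.  Under the defaults the three ICCs land near 0.7 / 0.75 / 0.87,
  in the plausible range for trained neuroradiologists; they are
  emergent, not calibrated, since reliability statistics from real reader
  panels cannot be recomputed without raw ratings.
* **Non-evaluability** is independent of fracture status by default.
  Whether detector failures correlate with fracture burden is unknowable
  from marginal counts, so the generator exposes
  `nonevaluable_or_fractured`, an odds multiplier on the non-evaluable
  rate of fractured patients, defaulting to 1 (independence).
* **Detector model.** The detector is simulated at the patient level only,
  keyed to the patient's most severe fracture — matching a detector that
  reports per scan, not per level.  Per-level detection is deliberately
  not modelled; nothing downstream consumes it.
* **Reproducibility.** One root seed; each patient draws from its own
  substream (`seed` spaced by a fixed multiplier), so enlarging the cohort
  never reshuffles earlier patients, and identical configurations produce
  byte-identical cohorts.

What the generator does *not* emulate: image content and scanner
differences, reader drift over time, correlation between readers beyond
the shared truth (readers err independently given the truth), per-level
detector behaviour, and any dependence of demographics on fracture status
other than the prior-VCF flag.  Passing tests on synthetic data therefore
validate the *statistical machinery* — estimators, intervals,
adjudication logic, bootstrap — under the assumed generating process; they
say nothing about how a real detector behaves on real scans.

## The deterministic fixture

`load_paper_fixture()` rebuilds a patient-level dataset from published
marginal counts alone, by constraint satisfaction rather than sampling.
The construction order is documented and deterministic:

1. The 2×2 tables force the strata: among detector-positives, 42
   mild-maximum patients (all single-fracture, since 149 − 107 = 42 and
   singles total 149 − 90 = 59), 17 moderate/severe singles, 90
   moderate/severe multis; analogously 48 / 5 / 25 among
   detector-negatives.
2. The vertebral-level table, split by detector arm and by grade class
   (grade ≥ 2 versus grade 1), gives per-level "slot" supplies.
3. Slots are dealt to patients by a level-major greedy: repeatedly take
   the level with the most remaining supply and give it to the eligible
   patient with the largest remaining demand, keeping each patient's
   levels distinct.  Severe patients (multis first) get one grade-2 slot
   upgraded to grade 3.
4. Every margin is then re-verified through the ordinary pipeline
   functions; any failure raises an error naming the violated constraint.

Within these constraints many datasets exist; any one of them is adequate
because every downstream statistic depends only on the asserted margins.
The 113 non-evaluable patients are constructed fracture-free: no primary
statistic uses their truth (the inclusive-sensitivity analysis imputes
instead of reading it), and marginal counts for them are not published.

One published inconsistency is deliberately not enforced: a
post-exclusion count reported alongside a percentage that does not match
it (161/996 printed as 14%); the ratio itself is used only to set the
generator's prior-VCF enrichment, never as a fixture constraint.

## Adjudication sub-cases

The dual-reader comparison flags three disagreement kinds; two sub-cases
needed decisions the design description leaves open:

* A level graded by one reader and omitted by the other is a *location*
  disagreement (and therefore also a grade disagreement) — it triggers
  adjudication even when both readers agree the patient is fractured.
* On any disagreement the senior's **entire reading** becomes the
  consensus, not a per-level merge.  A merge rule would have to invent
  semantics for levels the senior did not mention; the whole-reading
  override is the only rule that never manufactures findings no single
  reader reported.  Consequently the senior is consulted about the whole
  scan, not only the discordant levels.

`NONE`/grade-0 placeholder rows (the on-disk encoding of "this reader saw
nothing") are canonicalized to empty finding sets before comparison.

## Problem sizes in the test suite

The suite fixes its own simulation sizes as a balance between Monte-Carlo
resolution and runtime: marginal recovery pools 20 replicates of
n = 10,000; detector-parameter recovery and the level-histogram
goodness-of-fit use one n = 50,000 cohort (3-standard-error and α = 0.01
bands); ICC recovery uses the study-sized n = 1200; BCa coverage uses 200
replicates of n = 300 with 500 resamples.  Tolerances follow the
statistic: 3 binomial SEs for rates, ±0.05 for ICC point recovery, 1e-8 /
1e-10 for oracle agreement, exact equality for the fixture counts.

## Known limitations

* The inclusive-sensitivity imputation assumes equal prevalence among
  non-evaluable scans; a sensitivity analysis over
  `nonevaluable_or_fractured` is possible with the generator but no
  closed-form correction is provided.
* The LR intervals are delta-method intervals; they are asymptotic, and at
  very small cell counts the continuity-corrected point estimates shift
  noticeably (the correction is recorded in the output).
* The ICC treats ordinal severity as interval-scaled; a cumulative-link
  reliability model is out of scope.
* Stratified accuracy by scan region is available only by filtering the
  input tables; the package does not fit region-adjusted models.
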