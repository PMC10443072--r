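#' Configuration of the synthetic validation cohort
#'
#' Bundles every parameter of the synthetic cohort generator: disease
#' prevalence and severity structure, the spatial distribution of fractures
#' over vertebral levels, the operating characteristics of the patient-level
#' detector, the non-evaluable rate, the noise model of the primary readers
#' and of the senior (adjudicating) reader, and cohort demographics.
#'
#' All severity grades follow the Genant semiquantitative scale: 0 = no
#' fracture, 1 = mild, 2 = moderate, 3 = severe.
#'
#' @param n_patients Number of patients in the cohort.
#' @param prevalence_any Probability that a patient has at least one VCF.
#' @param grade_mix Length-3 probability vector over \{mild, moderate,
#'   severe\} for a fractured patient's most severe fracture; must sum to 1.
#' @param multi_fracture_prob Probability that a fractured patient has two or
#'   more fractures.
#' @param multi_extra_geom Success probability of the geometric law for the
#'   number of fractures beyond two in a multi-fracture patient (counts are
#'   2 + Geom, truncated at 17 total).
#' @param level_weights Length-17 probability vector over the vertebral
#'   levels T1..L5 (see [spine_levels()]); must sum to 1.
#' @param detector_sens_by_grade Length-3 vector: probability of a positive
#'   detector result given the patient's most severe fracture is mild,
#'   moderate, severe.
#' @param detector_fpr Probability of a positive detector result for a
#'   fracture-free patient.
#' @param nonevaluable_rate Probability the detector returns no determination
#'   for a scan, independent of fracture status (see
#'   `nonevaluable_or_fractured` for an optional dependence).
#' @param nonevaluable_or_fractured Odds multiplier applied to the
#'   non-evaluable odds of fractured patients; 1 (the default) makes
#'   non-evaluability independent of fracture status.
#' @param rater_presence_agreement Probability a primary reader detects a
#'   true fracture at a given level.
#' @param rater_grade_confusion 4x4 row-stochastic matrix over grades 0-3.
#'   Row `g + 1` is the distribution of the reported grade for a level of
#'   true grade `g`: row 1 governs spurious findings on intact levels, and
#'   for a detected true fracture the reported grade is drawn from its row
#'   (a 0 draw means the reader reports no fracture after all).
#' @param senior_presence_agreement,senior_grade_confusion The same noise
#'   model for the senior (adjudicating) reader, by default much milder.
#' @param perfect_senior If `TRUE` the senior reading equals the truth
#'   exactly, so the adjudicated reference can be compared against the
#'   generator truth in parameter-recovery studies.
#' @param female_fraction Probability a patient is female.
#' @param age_bins Length-5 probability vector over the age bins
#'   50-60, 61-70, 71-80, 81-90, 91+.
#' @param region_weights Length-3 probability vector over scan regions
#'   \{chest, abdomen_pelvis, both\}.
#' @param prior_vcf_prob_fractured,prior_vcf_prob_unfractured Probability of
#'   a previously documented VCF given the patient is / is not fractured
#'   (the enrichment arises because studies with previously verified VCF
#'   were deliberately over-sampled).
#' @param seed Integer root seed.  Each patient draws from an independent
#'   substream derived from it, so enlarging the cohort does not reshuffle
#'   earlier patients.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [default_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 1200,
                          prevalence_any = 227 / 1087,
                          grade_mix = c(90, 81, 56) / 227,
                          multi_fracture_prob = 115 / 227,
                          multi_extra_geom = 0.55,
                          level_weights = default_level_weights(),
                          detector_sens_by_grade = c(42 / 90, 60 / 81, 47 / 56),
                          detector_fpr = 82 / 860,
                          nonevaluable_rate = 113 / 1200,
                          nonevaluable_or_fractured = 1,
                          rater_presence_agreement = 0.85,
                          rater_grade_confusion = default_grade_confusion(),
                          senior_presence_agreement = 0.97,
                          senior_grade_confusion = default_grade_confusion(senior = TRUE),
                          perfect_senior = FALSE,
                          female_fraction = 588 / 1087,
                          age_bins = c(154, 311, 345, 215, 62) / 1087,
                          region_weights = c(962, 169, 69) / 1200,
                          prior_vcf_prob_fractured = 66 / 227,
                          prior_vcf_prob_unfractured = 25 / 860,
                          seed = 1L) {
  grade_dimnames <- list(paste0("true", 0:3), paste0("reported", 0:3))
  if (is.matrix(rater_grade_confusion))
    dimnames(rater_grade_confusion) <- grade_dimnames
  if (is.matrix(senior_grade_confusion))
    dimnames(senior_grade_confusion) <- grade_dimnames
  cfg <- list(
    n_patients = as.integer(n_patients),
    prevalence_any = prevalence_any,
    grade_mix = grade_mix,
    multi_fracture_prob = multi_fracture_prob,
    multi_extra_geom = multi_extra_geom,
    level_weights = level_weights,
    detector_sens_by_grade = detector_sens_by_grade,
    detector_fpr = detector_fpr,
    nonevaluable_rate = nonevaluable_rate,
    nonevaluable_or_fractured = nonevaluable_or_fractured,
    rater_presence_agreement = rater_presence_agreement,
    rater_grade_confusion = rater_grade_confusion,
    senior_presence_agreement = senior_presence_agreement,
    senior_grade_confusion = senior_grade_confusion,
    perfect_senior = isTRUE(perfect_senior),
    female_fraction = female_fraction,
    age_bins = age_bins,
    region_weights = region_weights,
    prior_vcf_prob_fractured = prior_vcf_prob_fractured,
    prior_vcf_prob_unfractured = prior_vcf_prob_unfractured,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Default cohort configuration matching the validation study marginals
#'
#' Returns the [cohort_config()] whose parameters reproduce, in expectation,
#' the marginals of the published validation cohort: 1200 patients, VCF
#' prevalence 227/1087 among evaluable scans, highest-grade mix
#' 90:81:56 (mild:moderate:severe), 115/227 multi-fracture probability,
#' non-evaluable rate 113/1200, detector false-positive rate 82/860, and
#' grade-specific detector sensitivities 42/90, 60/81, 47/56.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config` object.
#' @examples
#' cfg <- default_config()
#' round(cfg$prevalence_any, 4)     # 0.2088
#' round(cfg$detector_fpr, 4)       # 0.0953
#' @export
default_config <- function(...) cohort_config(...)

#' @rdname cohort_config
#' @export
default_level_weights <- function() {
  w <- c(2, 3, 8, 9, 20, 25, 29, 50, 32, 34, 62, 70, 64, 35, 19, 12, 8)
  stats::setNames(w / sum(w), spine_levels())
}

#' @rdname cohort_config
#' @param senior If `TRUE`, return the milder default confusion matrix used
#'   for the senior reader.
#' @export
default_grade_confusion <- function(senior = FALSE) {
  m <- if (senior) {
    rbind(
      c(0.999, 0.001, 0.000, 0.000),
      c(0.00, 0.95, 0.05, 0.00),
      c(0.00, 0.04, 0.92, 0.04),
      c(0.00, 0.00, 0.05, 0.95)
    )
  } else {
    rbind(
      c(0.9965, 0.0025, 0.0008, 0.0002),
      c(0.00, 0.80, 0.20, 0.00),
      c(0.00, 0.15, 0.70, 0.15),
      c(0.00, 0.00, 0.20, 0.80)
    )
  }
  dimnames(m) <- list(paste0("true", 0:3), paste0("reported", 0:3))
  m
}

validate_config <- function(cfg) {
  chk_prob <- function(x, nm, len = 1) {
    if (length(x) != len || anyNA(x) || any(x < 0) || any(x > 1))
      stopf("config field '%s' must be %d probabilit%s in [0, 1]",
            nm, len, if (len == 1) "y" else "ies")
  }
  chk_simplex <- function(x, nm, len) {
    chk_prob(x, nm, len)
    if (abs(sum(x) - 1) > 1e-12)
      stopf("config field '%s' must sum to 1 (got %.15f)", nm, sum(x))
  }
  if (cfg$n_patients < 0) stopf("n_patients must be non-negative")
  chk_prob(cfg$prevalence_any, "prevalence_any")
  chk_simplex(cfg$grade_mix, "grade_mix", 3)
  chk_prob(cfg$multi_fracture_prob, "multi_fracture_prob")
  chk_prob(cfg$multi_extra_geom, "multi_extra_geom")
  chk_simplex(cfg$level_weights, "level_weights", 17)
  chk_prob(cfg$detector_sens_by_grade, "detector_sens_by_grade", 3)
  chk_prob(cfg$detector_fpr, "detector_fpr")
  chk_prob(cfg$nonevaluable_rate, "nonevaluable_rate")
  if (cfg$nonevaluable_or_fractured <= 0)
    stopf("nonevaluable_or_fractured must be a positive odds multiplier")
  chk_prob(cfg$rater_presence_agreement, "rater_presence_agreement")
  chk_prob(cfg$senior_presence_agreement, "senior_presence_agreement")
  for (nm in c("rater_grade_confusion", "senior_grade_confusion")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(4, 4)) || anyNA(m) ||
        any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
      stopf("config field '%s' must be a 4x4 row-stochastic matrix over grades 0-3", nm)
  }
  chk_prob(cfg$female_fraction, "female_fraction")
  chk_simplex(cfg$age_bins, "age_bins", 5)
  chk_simplex(cfg$region_weights, "region_weights", 3)
  chk_prob(cfg$prior_vcf_prob_fractured, "prior_vcf_prob_fractured")
  chk_prob(cfg$prior_vcf_prob_unfractured, "prior_vcf_prob_unfractured")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic VCF validation cohort configuration\n")
  cat(sprintf("  patients: %d   prevalence(any VCF): %.4f   non-evaluable: %.4f\n",
              x$n_patients, x$prevalence_any, x$nonevaluable_rate))
  cat(sprintf("  grade mix (mild/moderate/severe): %s\n",
              paste(sprintf("%.3f", x$grade_mix), collapse = " / ")))
  cat(sprintf("  detector sens by grade: %s   fpr: %.4f\n",
              paste(sprintf("%.3f", x$detector_sens_by_grade), collapse = " / "),
              x$detector_fpr))
  cat(sprintf("  reader presence agreement: %.2f   senior: %s\n",
              x$rater_presence_agreement,
              if (x$perfect_senior) "perfect" else
                sprintf("agreement %.2f", x$senior_presence_agreement)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
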