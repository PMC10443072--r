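#' Severity-threshold comparison rules
#'
#' The four dichotomizations of the adjudicated reference used in the
#' validation analysis: any VCF (Genant grade >= 1) versus none; moderate or
#' severe (grade >= 2) versus mild or none; severe (grade 3) versus all
#' others; and two or more fractures versus none/one.
#'
#' @param name One of `"any"`, `"moderate_or_severe"`, `"severe"`,
#'   `"two_or_more"`.
#' @return An object of class `comparison_rule`: a list with the rule
#'   `name`, a human-readable `label`, and `predicate`, a function mapping a
#'   reference data frame (see [build_reference()]) to a logical
#'   reference-positive vector.
#' @examples
#' rule <- comparison_rule("moderate_or_severe")
#' rule$label
#' @export
comparison_rule <- function(name = c("any", "moderate_or_severe", "severe",
                                     "two_or_more")) {
  name <- match.arg(name)
  spec <- switch(name,
    any = list(label = "Mild, moderate, or severe versus no VCF",
               predicate = function(ref) ref$max_grade >= 1L),
    moderate_or_severe = list(
      label = "Moderate or severe versus mild or no VCF",
      predicate = function(ref) ref$max_grade >= 2L),
    severe = list(label = "Severe versus mild, moderate, or no VCF",
                  predicate = function(ref) ref$max_grade == 3L),
    two_or_more = list(label = "Two or more fractures versus none/one VCF",
                       predicate = function(ref) ref$n_fractures >= 2L)
  )
  structure(c(list(name = name), spec), class = "comparison_rule")
}

#' Cross-tabulate the reference standard against the index test
#'
#' Builds the 2x2 table of reference-positive/negative (under a severity
#' comparison rule) against the patient-level detector result.
#' Non-evaluable patients are excluded from the counts and tallied
#' separately, mirroring the primary analysis base of evaluable scans.
#'
#' @param refs Reference data frame from [build_reference()] (or any data
#'   frame with `patient_id`, `max_grade`, `n_fractures`).
#' @param index Data frame with `patient_id` and `result` in
#'   \{`positive`, `negative`, `non_evaluable`\}; every reference patient
#'   must appear.
#' @param rule A [comparison_rule()] or its name.
#' @return An object of class `table2x2`: list with counts `tp`, `fn`,
#'   `fp`, `tn`, the `rule`, and `n_excluded_nonevaluable`.
#' @examples
#' fix <- load_paper_fixture()
#' build_table(fix$reference, fix$index, "any")   # 149 / 78 / 82 / 778
#' @export
build_table <- function(refs, index, rule = "any") {
  if (is.character(rule)) rule <- comparison_rule(rule)
  stopifnot(inherits(rule, "comparison_rule"))
  pos <- match(refs$patient_id, index$patient_id)
  if (anyNA(pos)) {
    miss <- refs$patient_id[is.na(pos)]
    stopf("patient(s) in the reference but missing from the index test: %s%s",
          paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else "")
  }
  result <- index$result[pos]
  evaluable <- result != "non_evaluable"
  ref_pos <- rule$predicate(refs)
  alg_pos <- result == "positive"
  t <- list(
    tp = sum(evaluable & ref_pos & alg_pos),
    fn = sum(evaluable & ref_pos & !alg_pos),
    fp = sum(evaluable & !ref_pos & alg_pos),
    tn = sum(evaluable & !ref_pos & !alg_pos),
    rule = rule,
    n_excluded_nonevaluable = sum(!evaluable)
  )
  class(t) <- "table2x2"
  t
}

#' @export
print.table2x2 <- function(x, ...) {
  cat(sprintf("2x2 table: %s\n", x$rule$label))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(reference = c("positive", "negative"),
                              algorithm = c("positive", "negative")))
  print(m)
  cat(sprintf("(%d non-evaluable patient(s) excluded)\n",
              x$n_excluded_nonevaluable))
  invisible(x)
}

#' Per-vertebral-level sensitivity counts
#'
#' For each of the 17 vertebral levels, counts the patients with an
#' adjudicated fracture of at least `min_grade` at that level, and among
#' them those with a positive patient-level detector result.  Because the
#' detector does not localize fractures, this crosses a vertebral-level
#' reference with a patient-level index result; a multi-fracture patient
#' contributes to every level at which it is fractured.  Non-evaluable
#' patients are excluded.
#'
#' @param refs Reference data frame from [build_reference()] (must carry the
#'   17 per-level grade columns).
#' @param index Index-test data frame (`patient_id`, `result`).
#' @param min_grade 1 (any VCF at the level) or 2 (moderate or severe at the
#'   level).
#' @param level Confidence level for the exact binomial CI on each row.
#' @return Data frame with one row per level: `level`,
#'   `n_reference_positive`, `n_algo_positive`, `sensitivity`, `ci_low`,
#'   `ci_high` (the latter three `NA` where no reference-positive patient
#'   exists).
#' @examples
#' fix <- load_paper_fixture()
#' tab <- vertebral_sensitivity_table(fix$reference, fix$index, min_grade = 1)
#' tab[tab$level == "T8", ]   # 50 reference-positive, 32 detector-positive
#' @export
vertebral_sensitivity_table <- function(refs, index, min_grade = 1,
                                        level = 0.95) {
  if (!min_grade %in% c(1, 2))
    stopf("min_grade must be 1 (any) or 2 (moderate or severe)")
  lv <- spine_levels()
  missing <- setdiff(lv, names(refs))
  if (length(missing))
    stopf("reference lacks per-level grade column(s): %s",
          paste(missing, collapse = ", "))
  pos <- match(refs$patient_id, index$patient_id)
  if (anyNA(pos))
    stopf("patient(s) in the reference but missing from the index test")
  result <- index$result[pos]
  evaluable <- result != "non_evaluable"
  alg_pos <- result == "positive"
  n_ref <- integer(17); n_alg <- integer(17)
  for (j in seq_along(lv)) {
    at_level <- evaluable & refs[[lv[j]]] >= min_grade
    n_ref[j] <- sum(at_level)
    n_alg[j] <- sum(at_level & alg_pos)
  }
  sens <- ifelse(n_ref > 0, n_alg / n_ref, NA_real_)
  ci <- t(vapply(seq_along(lv), function(j) {
    if (n_ref[j] == 0) return(c(NA_real_, NA_real_))
    e <- exact_binomial_ci(n_alg[j], n_ref[j], level = level)
    c(e$ci_low, e$ci_high)
  }, numeric(2)))
  data.frame(level = lv, n_reference_positive = n_ref,
             n_algo_positive = n_alg, sensitivity = sens,
             ci_low = ci[, 1], ci_high = ci[, 2],
             stringsAsFactors = FALSE)
}
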