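# End-to-end orchestration: adjudication -> contingency -> accuracy ->
# reliability, with a formatted study report and CSV artifacts.

rules_all <- c("any", "moderate_or_severe", "severe", "two_or_more")

# Accuracy/LR/inclusive-sensitivity block for an adjudicated reference.
analyze_reference <- function(reference, index, level = 0.95) {
  tables <- lapply(rules_all, function(r) build_table(reference, index, r))
  names(tables) <- rules_all
  accuracy <- do.call(rbind, lapply(rules_all, function(r) {
    cbind(rule = r, accuracy_summary(tables[[r]], level = level))
  }))
  lrs <- do.call(rbind, lapply(rules_all, function(r) {
    cbind(rule = r, likelihood_ratios(tables[[r]], level = level))
  }))
  n_total <- nrow(index)
  n_evaluable <- sum(index$result != "non_evaluable")
  inclusive <- do.call(rbind, lapply(c("any", "moderate_or_severe"), function(r) {
    e <- inclusive_sensitivity(tables[[r]], n_total, n_evaluable, level = level)
    data.frame(rule = r, point = e$point, ci_low = e$ci_low,
               ci_high = e$ci_high, numerator = e$numerator,
               denominator = e$denominator, stringsAsFactors = FALSE)
  }))
  vertebral <- list(
    any = vertebral_sensitivity_table(reference, index, 1, level = level),
    moderate_or_severe = vertebral_sensitivity_table(reference, index, 2,
                                                     level = level)
  )
  list(tables = tables, accuracy = accuracy, lrs = lrs,
       inclusive = inclusive, vertebral = vertebral,
       n_total = n_total, n_evaluable = n_evaluable)
}

demographics_summary <- function(demographics, index) {
  if (is.null(demographics)) return(NULL)
  ev_ids <- index$patient_id[index$result != "non_evaluable"]
  d <- demographics[demographics$patient_id %in% ev_ids, , drop = FALSE]
  bins <- c("50-60", "61-70", "71-80", "81-90", "91+")
  bin_of <- cut(d$age_years, c(49, 60, 70, 80, 90, Inf), labels = bins)
  list(n_total = nrow(demographics), n_evaluable = nrow(d),
       n_female = sum(d$sex == "F"),
       age_median = stats::median(d$age_years),
       age_range = range(d$age_years),
       age_iqr = unname(stats::quantile(d$age_years, c(0.25, 0.75))),
       age_bins = table(bin_of),
       regions = table(demographics$region))
}

fracture_distribution <- function(reference, index) {
  ev <- index$result[match(reference$patient_id, index$patient_id)] !=
    "non_evaluable"
  alg_pos <- index$result[match(reference$patient_id, index$patient_id)] ==
    "positive"
  r <- reference[ev, , drop = FALSE]
  list(n_evaluable = sum(ev),
       algo_positive = sum(alg_pos & ev),
       radiologist_positive = sum(r$any_vcf),
       n_fractures = c(none = sum(r$n_fractures == 0),
                       one = sum(r$n_fractures == 1),
                       two_or_more = sum(r$n_fractures >= 2)),
       highest_grade = c(none = sum(r$max_grade == 0),
                         mild = sum(r$max_grade == 1),
                         moderate = sum(r$max_grade == 2),
                         severe = sum(r$max_grade == 3)))
}

#' Run the full validation pipeline
#'
#' Executes the complete analysis in order: adjudicated reference standard
#' from the paired readings, 2x2 tables under the four severity rules,
#' operating characteristics with exact CIs and likelihood ratios,
#' non-evaluable-inclusive sensitivity, per-vertebral-level sensitivity,
#' and (optionally) the three-outcome inter-rater reliability suite.
#'
#' @param input A `vcf_cohort` from [generate_cohort()], a directory
#'   written by [write_cohort()], or a list with elements `readings`,
#'   `index` and optionally `demographics`.
#' @param level Confidence level for all intervals.
#' @param reliability Run the ICC suite (the slowest step)?
#' @param n_boot,seed Bootstrap controls passed to [icc_suite()].
#' @param out_dir If non-`NULL`, write `reference.csv`, `table3.csv`,
#'   `table4.csv`, `accuracy.csv` and (when computed) `reliability.csv`
#'   there.  All computation happens before the first file is written, so a
#'   failing run leaves no partial artifacts.
#' @param verbose Log stage counts via [message()].
#' @return An object of class `study_report`; its `print` method renders
#'   the cohort, fracture-distribution, performance and reliability blocks.
#' @export
run_pipeline <- function(input, level = 0.95, reliability = TRUE,
                         n_boot = 1000, seed = 1, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- NULL
  if (inherits(input, "vcf_cohort")) {
    cfg <- input$config
    data <- input[c("readings", "index", "demographics")]
  } else if (is.character(input) && length(input) == 1) {
    data <- read_cohort(input)
  } else if (is.list(input) && all(c("readings", "index") %in% names(input))) {
    data <- input
  } else {
    stopf("'input' must be a vcf_cohort, a cohort directory, or a list with readings and index")
  }

  say("pipeline: %d patients, %d non-evaluable",
      nrow(data$index), sum(data$index$result == "non_evaluable"))
  reference <- build_reference(data$readings)
  say("reference standard: %d patients adjudicated by the senior reader",
      attr(reference, "n_adjudicated"))

  acc <- analyze_reference(reference, data$index, level = level)
  say("contingency: %d evaluable, %d excluded as non-evaluable",
      acc$n_evaluable, acc$n_total - acc$n_evaluable)

  rel <- NULL
  if (reliability) {
    suite <- icc_suite(data$readings, n_boot = n_boot, seed = seed,
                       level = level)
    rel <- reliability_table(suite)
    say("reliability: ICC presence %.2f, severity %.2f, count %.2f",
        rel$icc[1], rel$icc[2], rel$icc[3])
  }

  report <- structure(list(
    demographics = demographics_summary(data$demographics, data$index),
    fractures = fracture_distribution(reference, data$index),
    reference = reference,
    index = data$index,
    tables = acc$tables,
    accuracy = acc$accuracy,
    lrs = acc$lrs,
    inclusive = acc$inclusive,
    vertebral = acc$vertebral,
    reliability = rel,
    n_total = acc$n_total,
    n_evaluable = acc$n_evaluable,
    n_adjudicated = attr(reference, "n_adjudicated"),
    provenance = list(
      config_hash = if (!is.null(cfg)) config_hash(cfg),
      seed = seed,
      version = as.character(utils::packageVersion("vcfaccuracy"))
    )
  ), class = "study_report")

  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

#' Write the pipeline's CSV artifacts
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report_artifacts <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory '%s'", dir)
  t3 <- do.call(rbind, lapply(names(report$tables), function(r) {
    t <- report$tables[[r]]
    data.frame(rule = r, tp = t$tp, fn = t$fn, fp = t$fp, tn = t$tn,
               n_excluded_nonevaluable = t$n_excluded_nonevaluable,
               stringsAsFactors = FALSE)
  }))
  t4 <- rbind(cbind(min_grade = 1L, report$vertebral$any),
              cbind(min_grade = 2L, report$vertebral$moderate_or_severe))
  paths <- c(reference = file.path(dir, "reference.csv"),
             table3 = file.path(dir, "table3.csv"),
             table4 = file.path(dir, "table4.csv"),
             accuracy = file.path(dir, "accuracy.csv"))
  utils::write.csv(report$reference, paths["reference"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(t3, paths["table3"], row.names = FALSE, quote = FALSE)
  utils::write.csv(t4, paths["table4"], row.names = FALSE, quote = FALSE)
  acc <- rbind(report$accuracy,
               data.frame(rule = report$lrs$rule,
                          statistic = report$lrs$statistic,
                          numerator = NA_integer_, denominator = NA_integer_,
                          point = report$lrs$point, ci_low = report$lrs$ci_low,
                          ci_high = report$lrs$ci_high, method = "log_ratio",
                          stringsAsFactors = FALSE))
  utils::write.csv(acc, paths["accuracy"], row.names = FALSE, quote = FALSE)
  if (!is.null(report$reliability)) {
    paths <- c(paths, reliability = file.path(dir, "reliability.csv"))
    utils::write.csv(report$reliability, paths["reliability"],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Render a study report as text
#'
#' Deterministic plain-text rendering (the layout of the published cohort,
#' fracture-distribution, performance and vertebral-level tables): counts
#' with integer percentages, proportions at 2 decimals.
#'
#' @param report A `study_report`.
#' @return Character vector of lines.
#' @export
format_study_report <- function(report) {
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  pct <- function(k, n) round_half_away(100 * k / n)

  push("== Cohort ==")
  d <- report$demographics
  if (!is.null(d)) {
    push("Total patients: %d", d$n_total)
    push("Patients with non-missing algorithm result: %d", d$n_evaluable)
    push("Female: %d (%d%%)", d$n_female, pct(d$n_female, d$n_evaluable))
    push("Age: median %d (range %d-%d; IQR %d-%d)", d$age_median,
         d$age_range[1], d$age_range[2], d$age_iqr[1], d$age_iqr[2])
    for (b in names(d$age_bins))
      push("  %-6s %4d (%d%%)", b, d$age_bins[[b]],
           pct(d$age_bins[[b]], d$n_evaluable))
  } else {
    push("Total patients: %d (evaluable %d)", report$n_total,
         report$n_evaluable)
  }

  f <- report$fractures
  push("")
  push("== Fracture distribution (algorithm-evaluable, n = %d) ==",
       f$n_evaluable)
  push("Algorithm diagnosis of VCF:    %4d (%d%%)", f$algo_positive,
       pct(f$algo_positive, f$n_evaluable))
  push("Radiologist diagnosis of VCF:  %4d (%d%%)", f$radiologist_positive,
       pct(f$radiologist_positive, f$n_evaluable))
  push("Fracture count:  none %d / one %d / two or more %d",
       f$n_fractures[["none"]], f$n_fractures[["one"]],
       f$n_fractures[["two_or_more"]])
  push("Highest grade:   mild %d / moderate %d / severe %d",
       f$highest_grade[["mild"]], f$highest_grade[["moderate"]],
       f$highest_grade[["severe"]])

  push("")
  push("== Detector performance (reference standard: adjudicated radiologists) ==")
  for (r in names(report$tables)) {
    t <- report$tables[[r]]
    push("%s:", t$rule$label)
    push("  tp %d  fn %d  fp %d  tn %d  (non-evaluable excluded: %d)",
         t$tp, t$fn, t$fp, t$tn, t$n_excluded_nonevaluable)
    a <- report$accuracy[report$accuracy$rule == r, ]
    for (i in seq_len(nrow(a)))
      push("  %-11s %3d/%3d = %.2f (95%% CI %.2f-%.2f)", a$statistic[i],
           a$numerator[i], a$denominator[i],
           round_half_away(a$point[i], 2), round_half_away(a$ci_low[i], 2),
           round_half_away(a$ci_high[i], 2))
    l <- report$lrs[report$lrs$rule == r, ]
    for (i in seq_len(nrow(l)))
      push("  %-11s %.2f (95%% CI %.2f-%.2f)", l$statistic[i],
           round_half_away(l$point[i], 2), round_half_away(l$ci_low[i], 2),
           round_half_away(l$ci_high[i], 2))
  }
  push("")
  for (i in seq_len(nrow(report$inclusive))) {
    push("Inclusive sensitivity (%s, non-evaluable counted against): %.2f",
         report$inclusive$rule[i], round_half_away(report$inclusive$point[i], 2))
  }

  push("")
  push("== Sensitivity by vertebral level (patient-level detector result) ==")
  push("%-6s %28s  %28s", "level", "any VCF", "moderate or severe VCF")
  va <- report$vertebral$any; vm <- report$vertebral$moderate_or_severe
  fmt_row <- function(v, j) {
    if (v$n_reference_positive[j] == 0) return(sprintf("%28s", "-"))
    sprintf("%3d/%3d = %.2f (%.2f-%.2f)", v$n_algo_positive[j],
            v$n_reference_positive[j], round_half_away(v$sensitivity[j], 2),
            round_half_away(v$ci_low[j], 2), round_half_away(v$ci_high[j], 2))
  }
  for (j in seq_len(nrow(va)))
    push("%-6s %s  %s", va$level[j], fmt_row(va, j), fmt_row(vm, j))

  if (!is.null(report$reliability)) {
    push("")
    push("== Inter-rater reliability (initial readings, 2 of 3 readers) ==")
    rl <- report$reliability
    for (i in seq_len(nrow(rl)))
      push("ICC %-9s %.2f (95%% BCa CI %.2f-%.2f; %d bootstrap samples)",
           rl$outcome[i], round_half_away(rl$icc[i], 2),
           round_half_away(rl$ci_low[i], 2), round_half_away(rl$ci_high[i], 2),
           rl$n_boot[i])
  }

  push("")
  p <- report$provenance
  push("provenance: version %s, seed %d%s", p$version, p$seed,
       if (!is.null(p$config_hash)) sprintf(", config %s", p$config_hash) else "")
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_study_report(x), sep = "\n")
  invisible(x)
}
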