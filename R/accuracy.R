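#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities at `alpha/2` in each tail, via
#' the standard beta-quantile form of the Clopper-Pearson interval.  The
#' bounds are degenerate by construction: `ci_low = 0` when `k = 0` and
#' `ci_high = 1` when `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return An object of class `proportion_estimate`: list with `numerator`,
#'   `denominator`, `point`, `ci_low`, `ci_high`, `level`, `method`.
#' @examples
#' exact_binomial_ci(149, 227)   # 0.66 (0.59-0.72)
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n))
    stopf("k and n must be single non-missing counts")
  if (n < 1) stopf("n must be at least 1")
  if (k < 0 || k > n) stopf("k must satisfy 0 <= k <= n")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(numerator = as.integer(k), denominator = as.integer(n),
                 point = k / n, ci_low = lo, ci_high = hi, level = level,
                 method = "clopper_pearson"),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%d/%d = %.*f (%.0f%% CI %.*f-%.*f, %s)\n",
              x$numerator, x$denominator, digits, x$point, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high, x$method))
  invisible(x)
}

#' Operating characteristics of a 2x2 table with exact CIs
#'
#' Sensitivity, specificity, and positive/negative predictive values at the
#' study prevalence, each with its Clopper-Pearson interval.
#'
#' @param t A [build_table()] result (class `table2x2`).
#' @param level Confidence level.
#' @param strict If `TRUE`, a statistic whose margin is zero raises an error
#'   naming the margin; otherwise it is returned with `NA` estimates.
#' @return Data frame with one row per statistic: `statistic`, `numerator`,
#'   `denominator`, `point`, `ci_low`, `ci_high`, `method`.
#' @examples
#' fix <- load_paper_fixture()
#' accuracy_summary(build_table(fix$reference, fix$index, "any"))
#' @export
accuracy_summary <- function(t, level = 0.95, strict = FALSE) {
  stopifnot(inherits(t, "table2x2"))
  defs <- list(
    sensitivity = c(t$tp, t$tp + t$fn),
    specificity = c(t$tn, t$fp + t$tn),
    ppv = c(t$tp, t$tp + t$fp),
    npv = c(t$tn, t$fn + t$tn)
  )
  rows <- lapply(names(defs), function(nm) {
    k <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      if (strict)
        stopf("%s is undefined: its denominator margin is zero", nm)
      return(data.frame(statistic = nm, numerator = k, denominator = n,
                        point = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, method = "clopper_pearson",
                        stringsAsFactors = FALSE))
    }
    e <- exact_binomial_ci(k, n, level = level)
    data.frame(statistic = nm, numerator = k, denominator = n,
               point = e$point, ci_low = e$ci_low, ci_high = e$ci_high,
               method = "clopper_pearson", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Likelihood ratios with log-scale confidence intervals
#'
#' Positive and negative likelihood ratios of the index test,
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, with intervals
#' symmetric on the log scale from the standard two-proportion-ratio
#' (delta-method) variance, e.g.
#' `var(log LR+) = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` --- the interval a
#' log-link binomial regression of positivity on reference status
#' reproduces.
#'
#' @param t A `table2x2`.
#' @param level Confidence level.
#' @param strict If `TRUE`, a zero cell raises an error; otherwise 0.5 is
#'   added to all four cells for the ratio estimates (never for exact CIs
#'   elsewhere) and the correction is recorded in the output.
#' @return Data frame with rows `lr_pos` and `lr_neg`: `point`, `ci_low`,
#'   `ci_high`, `log_se`, `method`, `continuity_corrected`.
#' @examples
#' fix <- load_paper_fixture()
#' likelihood_ratios(build_table(fix$reference, fix$index, "any"))  # LR+ 6.88
#' @export
likelihood_ratios <- function(t, level = 0.95, strict = FALSE) {
  stopifnot(inherits(t, "table2x2"))
  cells <- c(tp = t$tp, fn = t$fn, fp = t$fp, tn = t$tn)
  corrected <- any(cells == 0)
  if (corrected && strict)
    stopf("zero cell(s) in the 2x2 table (%s): likelihood ratio undefined in strict mode",
          paste(names(cells)[cells == 0], collapse = ", "))
  if (corrected) cells <- cells + 0.5
  tp <- cells["tp"]; fn <- cells["fn"]; fp <- cells["fp"]; tn <- cells["tn"]
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  z <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(name, point, log_se) {
    data.frame(statistic = name, point = point,
               ci_low = exp(log(point) - z * log_se),
               ci_high = exp(log(point) + z * log_se),
               log_se = log_se, method = "log_ratio",
               continuity_corrected = corrected, stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("lr_pos", sens / (1 - spec),
        sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))),
    one("lr_neg", (1 - sens) / spec,
        sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)))
  )
  rownames(out) <- NULL
  out
}

#' Sensitivity inclusive of non-evaluable scans
#'
#' Re-estimates sensitivity counting scans the detector could not evaluate
#' against it, under the assumption that reference-positivity has the same
#' prevalence among non-evaluable as among evaluable scans.  The point
#' estimate is the evaluable-scan sensitivity scaled by the evaluable
#' fraction, `sens * n_evaluable / n_total`; for the interval, the expected
#' number of reference-positive patients among the non-evaluable scans,
#' `(tp + fn) * (n_total - n_evaluable) / n_evaluable` (rounded), is added
#' to the denominator with zero added to the numerator, and a
#' Clopper-Pearson interval is taken on the augmented counts.
#'
#' @param t A `table2x2` built on the evaluable patients.
#' @param n_total Total scans, including non-evaluable.
#' @param n_evaluable Evaluable scans (`tp + fn + fp + tn` of `t`).
#' @param level Confidence level.
#' @return A `proportion_estimate` (the `point` uses the multiplicative
#'   form; `numerator`/`denominator` are the augmented counts).
#' @examples
#' fix <- load_paper_fixture()
#' t_any <- build_table(fix$reference, fix$index, "any")
#' inclusive_sensitivity(t_any, n_total = 1200, n_evaluable = 1087)  # ~0.59
#' @export
inclusive_sensitivity <- function(t, n_total, n_evaluable, level = 0.95) {
  stopifnot(inherits(t, "table2x2"))
  if (n_evaluable == 0) stopf("n_evaluable must be positive")
  if (n_evaluable > n_total) stopf("n_evaluable cannot exceed n_total")
  n_pos <- t$tp + t$fn
  if (n_pos == 0) stopf("no reference-positive patients in the table")
  sens <- t$tp / n_pos
  imputed <- round(n_pos * (n_total - n_evaluable) / n_evaluable)
  e <- exact_binomial_ci(t$tp, n_pos + imputed, level = level)
  e$point <- sens * n_evaluable / n_total
  e$method <- "clopper_pearson_augmented"
  e
}

#' Sample size for likelihood-ratio precision
#'
#' Smallest cohort size `n` such that, at the anticipated operating
#' characteristics and prevalence, the expected lower bound of the
#' log-scale CI for the positive likelihood ratio,
#' `exp(log LR+ - z * SE(n))`, is at least `exclude_value`.  `SE(n)` uses
#' the two-proportion-ratio variance at the expected cell counts
#' (`n * prevalence * sens`, etc.), so the required `n` has the closed form
#' `n = c * z^2 / log(LR+ / exclude_value)^2` with
#' `c = 1/(p*sens) - 1/p + 1/((1-p)(1-spec)) - 1/(1-p)`.
#'
#' @param sens,spec Anticipated sensitivity and specificity.
#' @param prevalence Anticipated prevalence of the target condition
#'   (default 0.15, within the range reported by prior prevalence studies).
#' @param exclude_value The LR+ value the lower confidence bound must
#'   exclude; must be below `sens / (1 - spec)`.
#' @param level Confidence level.
#' @return The required sample size (integer scalar).
#' @examples
#' sample_size_for_lr(0.9, 0.91, exclude_value = 8)   # about 1000 patients
#' @export
sample_size_for_lr <- function(sens, spec, prevalence = 0.15,
                               exclude_value, level = 0.95) {
  if (sens <= 0 || sens >= 1 || spec <= 0 || spec >= 1)
    stopf("sens and spec must be in (0, 1)")
  if (prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must be in (0, 1)")
  lr <- sens / (1 - spec)
  if (exclude_value <= 0 || exclude_value >= lr)
    stopf("exclude_value must be in (0, LR+) = (0, %.3f)", lr)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cc <- 1 / (prevalence * sens) - 1 / prevalence +
    1 / ((1 - prevalence) * (1 - spec)) - 1 / (1 - prevalence)
  slack <- log(lr / exclude_value)
  n <- ceiling(cc * z^2 / slack^2)
  # guard the ceiling against boundary rounding: n is minimal by construction
  bound_ok <- function(n) sqrt(cc / n) * z <= slack
  while (!bound_ok(n)) n <- n + 1L
  while (n > 1L && bound_ok(n - 1L)) n <- n - 1L
  as.integer(n)
}
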