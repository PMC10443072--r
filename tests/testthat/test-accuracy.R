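test_that("Clopper-Pearson bounds hit printed values and degenerate cases", {
  expect_equal(exact_binomial_ci(0, 10)$ci_low, 0)
  expect_equal(exact_binomial_ci(10, 10)$ci_high, 1)
  e <- exact_binomial_ci(149, 227)
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(0.59, 0.72))
  e2 <- exact_binomial_ci(32, 50)
  expect_equal(round(c(e2$ci_low, e2$ci_high), 2), c(0.49, 0.77))
  expect_error(exact_binomial_ci(3, 0), "at least 1")
  expect_error(exact_binomial_ci(5, 4), "0 <= k <= n")
})

test_that("Clopper-Pearson agrees with binom.test across a grid", {
  for (n in c(1, 7, 30, 227, 1000)) {
    for (k in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      e <- exact_binomial_ci(k, n)
      bt <- stats::binom.test(k, n)$conf.int
      expect_equal(c(e$ci_low, e$ci_high), as.numeric(bt), tolerance = 1e-12)
    }
  }
})

test_that("exact intervals are conservative: empirical coverage >= nominal", {
  set.seed(71)
  bounds <- vapply(0:100, function(k) {
    e <- exact_binomial_ci(k, 100)
    c(e$ci_low, e$ci_high)
  }, numeric(2))
  for (p in c(0.05, 0.5, 0.9)) {
    k <- stats::rbinom(2000, 100, p)
    covered <- bounds[1, k + 1] <= p & p <= bounds[2, k + 1]
    expect_gte(mean(covered), 0.95)
  }
})

test_that("accuracy summaries reproduce the published operating characteristics", {
  fix <- paper_fix()
  t_any <- build_table(fix$reference, fix$index, "any")
  a <- accuracy_summary(t_any)
  get <- function(df, s) df[df$statistic == s, ]
  expect_equal(round(get(a, "sensitivity")$point, 2), 0.66)
  expect_equal(round(get(a, "specificity")$point, 2), 0.90)
  expect_equal(round(c(get(a, "specificity")$ci_low,
                       get(a, "specificity")$ci_high), 2), c(0.88, 0.92))

  t_ms <- build_table(fix$reference, fix$index, "moderate_or_severe")
  am <- accuracy_summary(t_ms)
  expect_equal(round(get(am, "sensitivity")$point, 2), 0.78)
  expect_equal(round(get(am, "specificity")$point, 2), 0.87)
  expect_equal(round(c(get(am, "sensitivity")$ci_low,
                       get(am, "sensitivity")$ci_high), 2), c(0.70, 0.85))

  perfect <- structure(list(tp = 5, fn = 0, fp = 0, tn = 5,
                            rule = comparison_rule("any"),
                            n_excluded_nonevaluable = 0L), class = "table2x2")
  expect_equal(accuracy_summary(perfect)$point, rep(1, 4))
})

test_that("likelihood ratios satisfy their algebraic identities", {
  fix <- paper_fix()
  for (rule in c("any", "moderate_or_severe")) {
    t <- build_table(fix$reference, fix$index, rule)
    lr <- likelihood_ratios(t)
    sens <- t$tp / (t$tp + t$fn); spec <- t$tn / (t$fp + t$tn)
    expect_equal(lr$point[1] * (1 - spec), sens, tolerance = 1e-12)
    expect_equal(lr$point[2] * spec, 1 - sens, tolerance = 1e-12)
    # diagnostic odds ratio identity
    expect_equal(lr$point[1] / lr$point[2],
                 (t$tp * t$tn) / (t$fn * t$fp), tolerance = 1e-12)
    # interval is symmetric on the log scale
    expect_equal(log(lr$ci_high[1]) - log(lr$point[1]),
                 log(lr$point[1]) - log(lr$ci_low[1]), tolerance = 1e-9)
  }
  # uninformative test: sens = spec = 0.5
  flat <- structure(list(tp = 20, fn = 20, fp = 20, tn = 20,
                         rule = comparison_rule("any"),
                         n_excluded_nonevaluable = 0L), class = "table2x2")
  expect_equal(likelihood_ratios(flat)$point, c(1, 1))
})

test_that("zero cells trigger the documented continuity rule", {
  t0 <- structure(list(tp = 10, fn = 5, fp = 0, tn = 100,
                       rule = comparison_rule("any"),
                       n_excluded_nonevaluable = 0L), class = "table2x2")
  expect_error(likelihood_ratios(t0, strict = TRUE), "zero cell")
  lr <- likelihood_ratios(t0)
  expect_true(all(lr$continuity_corrected))
  expect_true(is.finite(lr$point[1]))
  expect_equal(lr$point[1], (10.5 / 16) / (0.5 / 101))
})

test_that("inclusive sensitivity scales by the evaluable fraction", {
  fix <- paper_fix()
  t_any <- build_table(fix$reference, fix$index, "any")
  inc <- inclusive_sensitivity(t_any, n_total = 1200, n_evaluable = 1087)
  expect_equal(round(inc$point, 2), 0.59)
  expect_equal(inc$denominator, 227L + round(227 * 113 / 1087))

  # no attrition: identical to the plain sensitivity
  inc0 <- inclusive_sensitivity(t_any, 1087, 1087)
  plain <- exact_binomial_ci(t_any$tp, t_any$tp + t_any$fn)
  expect_equal(inc0$point, plain$point)
  expect_equal(c(inc0$ci_low, inc0$ci_high), c(plain$ci_low, plain$ci_high))

  # tp = 0: inclusive sensitivity is 0 regardless of attrition
  tz <- structure(list(tp = 0, fn = 12, fp = 3, tn = 85,
                       rule = comparison_rule("any"),
                       n_excluded_nonevaluable = 10L), class = "table2x2")
  expect_equal(inclusive_sensitivity(tz, 110, 100)$point, 0)
  expect_error(inclusive_sensitivity(t_any, 1200, 0), "positive")
})

test_that("the LR-precision sample size matches a grid-search oracle", {
  n <- sample_size_for_lr(0.9, 0.91, 0.15, exclude_value = 8)
  expect_gte(n, 800); expect_lte(n, 1200)

  # independent oracle: scan n and find the smallest satisfying the bound
  oracle <- function(sens, spec, p, excl, level = 0.95) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lr <- sens / (1 - spec)
    for (n in 1:5000) {
      tp <- n * p * sens; fn <- n * p * (1 - sens)
      fp <- n * (1 - p) * (1 - spec); tn <- n * (1 - p) * spec
      se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      if (exp(log(lr) - z * se) >= excl) return(n)
    }
    NA_integer_
  }
  cases <- list(c(0.9, 0.91, 0.15, 8), c(0.8, 0.9, 0.2, 5),
                c(0.66, 0.9, 0.21, 4), c(0.9, 0.91, 0.3, 8))
  for (cs in cases)
    expect_equal(sample_size_for_lr(cs[1], cs[2], cs[3], cs[4]),
                 oracle(cs[1], cs[2], cs[3], cs[4]), info = paste(cs, collapse = "/"))

  # monotone: more slack (smaller excluded value) needs fewer patients
  ns <- vapply(c(9, 8, 6, 4, 2), function(e)
    sample_size_for_lr(0.9, 0.91, 0.15, e), integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size_for_lr(0.9, 0.91, 0.15, 11), "exclude_value")
})
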