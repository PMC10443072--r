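test_that("degenerate rating patterns give the expected ICC limits", {
  # raters always identical per patient, outcomes varying across patients
  ratings <- data.frame(
    patient_id = rep(sprintf("P%03d", 1:50), each = 2),
    rater_id = rep(c("R1", "R2"), 50),
    outcome = rep(seq_len(50), each = 2))
  f <- fit_variance_components(ratings)
  expect_equal(f$icc, 1)
  expect_true(f$degenerate)

  # all outcomes identical: flagged degenerate with icc 1
  const <- ratings; const$outcome <- 3
  fc <- fit_variance_components(const)
  expect_true(fc$degenerate)
  expect_equal(fc$icc, 1)

  # pure noise, no subject effect: icc near 0
  noise <- simulate_ratings(2000, sigma2_subject = 0, sigma2_resid = 1, seed = 4)
  expect_lt(fit_variance_components(noise)$icc, 0.05)
})

test_that("REML matches lme4 on the two-of-three-raters design", {
  skip_if_not_installed("lme4")
  r <- simulate_ratings(400, sigma2_subject = 1, sigma2_resid = 3 / 7,
                        mu = 2, rater_effects = c(0, 0.3, -0.2), seed = 11)
  f <- fit_variance_components(r)
  m <- lme4::lmer(outcome ~ rater_id + (1 | patient_id), data = r, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma2_subject, vc$vcov[1], tolerance = 1e-6)
  expect_equal(f$sigma2_resid, vc$vcov[2], tolerance = 1e-6)
  expect_equal(unname(f$rater_effects), unname(lme4::fixef(m)),
               tolerance = 1e-6)
  # the estimate is the variance ratio by construction
  expect_equal(f$icc, f$sigma2_subject / (f$sigma2_subject + f$sigma2_resid),
               tolerance = 1e-12)
})

test_that("balanced complete designs reproduce the two-way ANOVA ICC", {
  r <- simulate_ratings(150, sigma2_subject = 1, sigma2_resid = 0.5,
                        rater_effects = c(0, 0.3, -0.2),
                        raters_per_patient = 3, seed = 5)
  f <- fit_variance_components(r)
  a <- summary(stats::aov(outcome ~ rater_id + Error(patient_id), data = r))
  msr <- a[["Error: patient_id"]][[1]]["Residuals", "Mean Sq"]
  mse <- a[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  icc_anova <- (msr - mse) / (msr + 2 * mse)
  expect_equal(f$icc, icc_anova, tolerance = 1e-8)
})

test_that("the ICC is invariant to location and positive scale changes", {
  r <- simulate_ratings(300, 1, 3 / 7, seed = 8)
  base <- fit_variance_components(r)$icc
  shifted <- r; shifted$outcome <- r$outcome + 100
  scaled <- r; scaled$outcome <- r$outcome * 7.3
  expect_equal(fit_variance_components(shifted)$icc, base, tolerance = 1e-10)
  expect_equal(fit_variance_components(scaled)$icc, base, tolerance = 1e-10)
  expect_gte(base, 0); expect_lte(base, 1)
})

test_that("BCa intervals are reproducible, bracket the point and handle constants", {
  r <- simulate_ratings(150, 1, 3 / 7, seed = 2)
  ci1 <- bca_ci(r, NULL, n_boot = 400, seed = 9)
  ci2 <- bca_ci(r, NULL, n_boot = 400, seed = 9)
  expect_identical(ci1[c("ci_low", "ci_high")], ci2[c("ci_low", "ci_high")])
  expect_lte(ci1$ci_low, ci1$point)
  expect_gte(ci1$ci_high, ci1$point)
  expect_gte(ci1$ci_low, 0); expect_lte(ci1$ci_high, 1)

  const <- bca_ci(r, function(d) 42, n_boot = 200, seed = 1)
  expect_equal(c(const$ci_low, const$ci_high), c(42, 42))
})

test_that("BCa endpoints agree with the boot package on the same statistic", {
  skip_if_not_installed("boot")
  r <- simulate_ratings(200, 1, 3 / 7, seed = 6)
  mine <- bca_ci(r, NULL, n_boot = 2000, seed = 13)

  # boot resamples rows of a patient-level frame; reuse our REML via a
  # long-format reconstruction, so only the BCa machinery differs
  wide <- data.frame(i = seq_len(200))
  rows <- split(seq_len(nrow(r)), factor(r$patient_id, levels = unique(r$patient_id)))
  stat <- function(d, idx) {
    take <- unlist(rows[d$i[idx]], use.names = FALSE)
    long <- data.frame(patient_id = rep(seq_along(idx), lengths(rows[d$i[idx]])),
                       rater_id = r$rater_id[take], outcome = r$outcome[take])
    fit_variance_components(long)$icc
  }
  set.seed(99)
  b <- boot::boot(wide, stat, R = 2000)
  bci <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(mine$ci_low, bci[1], tolerance = 0.02)
  expect_equal(mine$ci_high, bci[2], tolerance = 0.02)
})

test_that("bootstrap failures above 5% abort with diagnostics", {
  r <- simulate_ratings(100, 1, 3 / 7, seed = 3)
  flaky <- local({
    calls <- 0
    function(d) {
      calls <<- calls + 1
      if (calls %% 2 == 0) stop("boom")
      fit_variance_components(d)$icc
    }
  })
  expect_error(bca_ci(r, flaky, n_boot = 200, seed = 1), "5%")
})

test_that("reliability outcomes and the ICC suite behave on known inputs", {
  outc <- reliability_outcomes(tiny_readings())
  expect_equal(nrow(outc), 6L)
  a1 <- outc[outc$patient_id == "A" & outc$rater_id == "R1", ]
  expect_equal(c(a1$presence, a1$severity, a1$count), c(1L, 2L, 1L))
  b1 <- outc[outc$patient_id == "B" & outc$rater_id == "R1", ]
  expect_equal(c(b1$presence, b1$severity, b1$count), c(1L, 2L, 2L))
  c1 <- outc[outc$patient_id == "C" & outc$rater_id == "R1", ]
  expect_equal(c(c1$presence, c1$severity, c1$count), c(0L, 0L, 0L))

  # noiseless readers agree perfectly: all three ICCs are 1
  coh <- noiseless_cohort()
  suite <- icc_suite(coh$readings, n_boot = 200, seed = 1)
  expect_equal(vapply(suite, function(e) e$icc, numeric(1)),
               c(presence = 1, severity = 1, count = 1))
  tab <- reliability_table(suite)
  expect_equal(tab$outcome, c("presence", "severity", "count"))
  expect_true(all(tab$ci_low <= tab$icc & tab$icc <= tab$ci_high))
})

test_that("mild grade confusion with noisy presence makes severity more reliable", {
  # single fractures, perfect grading, noisy detection: detecting a fracture
  # at all is then the only source of disagreement, and grade dispersion
  # adds between-patient signal to the severity outcome only
  cfg <- default_config(
    n_patients = 1500, seed = 17,
    multi_fracture_prob = 0,
    rater_presence_agreement = 0.7,
    rater_grade_confusion = diag(4))
  coh <- generate_cohort(cfg)
  outc <- reliability_outcomes(coh$readings)
  icc_of <- function(nm) {
    fit_variance_components(data.frame(patient_id = outc$patient_id,
                                       rater_id = outc$rater_id,
                                       outcome = as.numeric(outc[[nm]])))$icc
  }
  expect_gte(icc_of("severity"), icc_of("presence"))
})
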