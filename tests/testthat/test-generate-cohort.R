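test_that("generation is deterministic and per-patient substreams are stable", {
  cfg <- default_config(n_patients = 150, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # growing the cohort must not reshuffle earlier patients
  big <- generate_cohort(default_config(n_patients = 300, seed = 11))
  expect_identical(a$index, big$index[1:150, ])
  expect_equal(a$truth, big$truth[big$truth$patient_id %in%
                                    a$index$patient_id, ],
               ignore_attr = TRUE)
  expect_identical(a$demographics, big$demographics[1:300 <= 150, ])
})

test_that("noiseless raters reproduce the truth; disease-free cohorts behave", {
  coh <- noiseless_cohort()
  for (rid in c("R1", "R2", "R3", "SENIOR")) {
    r <- coh$readings[coh$readings$reader_id == rid &
                        coh$readings$level != "NONE", ]
    truth_for <- coh$truth[coh$truth$patient_id %in% r$patient_id, ]
    expect_equal(r[order(r$patient_id, r$level), c("patient_id", "level", "grade")],
                 truth_for[order(truth_for$patient_id, truth_for$level), ],
                 ignore_attr = TRUE)
  }

  cfg0 <- default_config(n_patients = 2000, prevalence_any = 0, seed = 5)
  coh0 <- generate_cohort(cfg0)
  expect_identical(nrow(coh0$truth), 0L)
  n_pos <- sum(coh0$index$result == "positive")
  p <- cfg0$detector_fpr * (1 - cfg0$nonevaluable_rate)
  expect_lt(abs(n_pos - 2000 * p), 3 * sqrt(2000 * p * (1 - p)))
})

test_that("generated marginals recover the configured rates", {
  cfg <- default_config(n_patients = 10000)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  # pool 20 independent replicates of n = 10,000 and compare each observed
  # marginal with its configured value at 3 binomial standard errors
  n <- 0; nf <- 0; n_any <- 0; n_grade <- c(0, 0, 0); n_multi <- 0; n_ne <- 0
  for (rep in 1:20) {
    coh <- generate_cohort(default_config(n_patients = 10000, seed = 1000 + rep))
    tr <- truth_reference(coh)
    n <- n + nrow(tr)
    nf <- nf + sum(tr$any_vcf)
    n_any <- n_any + sum(tr$any_vcf)
    n_grade <- n_grade + tabulate(tr$max_grade[tr$any_vcf], 3)
    n_multi <- n_multi + sum(tr$n_fractures[tr$any_vcf] >= 2)
    n_ne <- n_ne + sum(coh$index$result == "non_evaluable")
  }
  expect_lt(abs(n_any / n - cfg$prevalence_any),
            3 * se(cfg$prevalence_any, n))
  for (g in 1:3)
    expect_lt(abs(n_grade[g] / nf - cfg$grade_mix[g]),
              3 * se(cfg$grade_mix[g], nf))
  expect_lt(abs(n_multi / nf - cfg$multi_fracture_prob),
            3 * se(cfg$multi_fracture_prob, nf))
  expect_lt(abs(n_ne / n - cfg$nonevaluable_rate),
            3 * se(cfg$nonevaluable_rate, n))
})

test_that("fracture levels follow the configured level distribution", {
  coh <- big_cohort()
  cfg <- coh$config
  obs <- table(factor(coh$truth$level, levels = spine_levels()))
  # goodness of fit of the empirical level histogram at alpha = 0.01;
  # multi-fracture levels are sampled without replacement within a patient,
  # so restrict to single-fracture patients, whose level is an i.i.d. draw
  # from the weights
  counts <- table(coh$truth$patient_id)
  singles <- coh$truth[coh$truth$patient_id %in%
                         names(counts)[counts == 1], ]
  obs1 <- table(factor(singles$level, levels = spine_levels()))
  gof <- stats::chisq.test(obs1, p = cfg$level_weights)
  expect_gt(gof$p.value, 0.01)
  # and the full histogram still concentrates where the weights do
  expect_equal(names(which.max(obs)), names(which.max(cfg$level_weights)))
})

test_that("cohorts round-trip losslessly through CSV and count non-evaluables", {
  coh <- generate_cohort(default_config(n_patients = 1200, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$readings, coh$readings)
  expect_identical(back$index, coh$index)
  expect_identical(back$demographics, coh$demographics)
  expect_identical(back$truth, coh$truth)

  n_ne <- sum(back$index$result == "non_evaluable")
  p <- 113 / 1200
  expect_lt(abs(n_ne - 113), 3 * sqrt(1200 * p * (1 - p)))

  # empty cohort: headers-only files
  empty <- generate_cohort(default_config(n_patients = 0))
  dir2 <- withr::local_tempdir()
  write_cohort(empty, dir2)
  expect_identical(nrow(read_cohort(dir2)$index), 0L)
  expect_identical(names(read_cohort(dir2)$readings),
                   c("patient_id", "reader_id", "level", "grade"))
})
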