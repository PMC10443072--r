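#!/usr/bin/env Rscript
# Step 3: diagnostic accuracy of the patient-level detector.
#
# Two runs of the contingency/accuracy analysis:
#   (a) the deterministic fixture reconstructed from the published table
#       counts -- this reproduces the reported operating characteristics
#       exactly, and
#   (b) the simulated cohort from steps 1-2.
# Writes table3.csv / table4.csv / accuracy.csv per run under results/.

library(vcfaccuracy)

analyze <- function(reference, index, tag, n_total) {
  dir <- file.path("results", tag)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rules <- c("any", "moderate_or_severe", "severe", "two_or_more")
  tables <- lapply(rules, function(r) build_table(reference, index, r))
  names(tables) <- rules

  t3 <- do.call(rbind, lapply(rules, function(r) {
    t <- tables[[r]]
    data.frame(rule = r, tp = t$tp, fn = t$fn, fp = t$fp, tn = t$tn)
  }))
  utils::write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE,
                   quote = FALSE)

  acc <- do.call(rbind, lapply(rules, function(r)
    cbind(rule = r, accuracy_summary(tables[[r]]))))
  lrs <- do.call(rbind, lapply(rules, function(r)
    cbind(rule = r, likelihood_ratios(tables[[r]]))))
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(lrs, file.path(dir, "likelihood_ratios.csv"),
                   row.names = FALSE, quote = FALSE)

  t4 <- rbind(cbind(min_grade = 1, vertebral_sensitivity_table(reference, index, 1)),
              cbind(min_grade = 2, vertebral_sensitivity_table(reference, index, 2)))
  utils::write.csv(t4, file.path(dir, "table4.csv"), row.names = FALSE,
                   quote = FALSE)

  t_any <- tables$any
  n_ev <- t_any$tp + t_any$fn + t_any$fp + t_any$tn
  inc <- inclusive_sensitivity(t_any, n_total, n_ev)
  sens <- acc[acc$rule == "any" & acc$statistic == "sensitivity", ]
  spec <- acc[acc$rule == "any" & acc$statistic == "specificity", ]
  cat(sprintf("[%s] any VCF: sensitivity %.2f (%.2f-%.2f), specificity %.2f (%.2f-%.2f)\n",
              tag, sens$point, sens$ci_low, sens$ci_high,
              spec$point, spec$ci_low, spec$ci_high))
  cat(sprintf("[%s] LR+ any %.2f, moderate/severe %.2f; inclusive sensitivity %.2f\n",
              tag, lrs$point[lrs$rule == "any" & lrs$statistic == "lr_pos"],
              lrs$point[lrs$rule == "moderate_or_severe" & lrs$statistic == "lr_pos"],
              inc$point))
}

fix <- load_paper_fixture()
analyze(fix$reference, fix$index, "paper_fixture", fix$n_total)

reference <- utils::read.csv("results/reference.csv",
                             colClasses = c(patient_id = "character"))
cohort <- read_cohort("results/cohort")
analyze(reference, cohort$index, "synthetic", nrow(cohort$index))

n_req <- sample_size_for_lr(sens = 0.9, spec = 0.91, prevalence = 0.15,
                            exclude_value = 8)
cat(sprintf("planned design: %d patients needed for the LR+ 95%% CI to exclude 8\n",
            n_req))
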