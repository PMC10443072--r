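#!/usr/bin/env Rscript
# Step 4: inter-rater reliability of the primary readers.
#
# Variance-components ICC (rater as fixed effect, patient as random
# intercept) with 95% BCa bootstrap intervals (1000 patient-block
# resamples) for the three outcomes of the initial readings: presence of
# at least one VCF, severity of the most severe VCF, and VCF count.
# Writes results/reliability.csv.

library(vcfaccuracy)

cohort <- read_cohort("results/cohort")
suite <- icc_suite(cohort$readings, n_boot = 1000, seed = 20230626)
tab <- reliability_table(suite)

for (i in seq_len(nrow(tab)))
  cat(sprintf("ICC %-9s %.2f (95%% BCa CI %.2f-%.2f)\n",
              tab$outcome[i], tab$icc[i], tab$ci_low[i], tab$ci_high[i]))

utils::write.csv(tab, "results/reliability.csv", row.names = FALSE,
                 quote = FALSE)
cat("wrote results/reliability.csv\n")
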