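#!/usr/bin/env Rscript
# Step 1: simulate the validation cohort.
#
# Generates a 1200-patient synthetic cohort whose marginals match the
# published study (prevalence 227/1087, grade mix 90:81:56, non-evaluable
# 113/1200, detector sensitivities 42/90, 60/81, 47/56, false-positive rate
# 82/860) and writes the three pipeline input tables plus the latent truth
# and the generating configuration under results/cohort/.

library(vcfaccuracy)

out_dir <- "results/cohort"
cfg <- default_config(n_patients = 1200, seed = 20230626)

coh <- generate_cohort(cfg)
paths <- write_cohort(coh, out_dir)
write_config(cfg, file.path(out_dir, "config.yaml"))

tr <- truth_reference(coh)
cat(sprintf("cohort: %d patients, %d (%.0f%%) with at least one true VCF\n",
            nrow(tr), sum(tr$any_vcf), 100 * mean(tr$any_vcf)))
cat(sprintf("index test: %d positive, %d negative, %d non-evaluable\n",
            sum(coh$index$result == "positive"),
            sum(coh$index$result == "negative"),
            sum(coh$index$result == "non_evaluable")))
cat("wrote:", paste(basename(paths), collapse = ", "),
    "and config.yaml to", out_dir, "\n")
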