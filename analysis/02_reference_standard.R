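#!/usr/bin/env Rscript
# Step 2: build the adjudicated radiologist reference standard.
#
# Reads the simulated readings (two primary neuroradiologists per patient
# from a pool of three, plus a senior reader), flags presence / grade /
# location disagreements, and resolves them with the senior reading.
# Writes the patient-level reference (any-VCF, max grade, fracture count,
# per-level grades) to results/reference.csv.

library(vcfaccuracy)

cohort <- read_cohort("results/cohort")
reference <- build_reference(cohort$readings)

n <- nrow(reference)
n_adj <- attr(reference, "n_adjudicated")
cat(sprintf("reference standard for %d patients\n", n))
cat(sprintf("primary readers disagreed on %d patients (%.0f%%); senior reading used\n",
            n_adj, 100 * n_adj / n))
cat(sprintf("fractured: %d patients; highest grade mild/moderate/severe = %d/%d/%d\n",
            sum(reference$any_vcf),
            sum(reference$max_grade == 1),
            sum(reference$max_grade == 2),
            sum(reference$max_grade == 3)))

utils::write.csv(reference, "results/reference.csv", row.names = FALSE,
                 quote = FALSE)
cat("wrote results/reference.csv\n")
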