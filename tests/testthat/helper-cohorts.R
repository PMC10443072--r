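# Shared, lazily built fixtures.  Expensive cohorts are generated once per
# test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) assign(name, expr, .fixture_cache)
  .fixture_cache[[name]]
}

paper_fix <- function() cached("paper_fix", load_paper_fixture())

# large default-parameter cohort for detector-recovery and level-histogram checks
big_cohort <- function() {
  cached("big50k", generate_cohort(default_config(n_patients = 50000,
                                                  seed = 424242)))
}

# noiseless readers + perfect senior: the adjudicated reference must equal truth
noiseless_cohort <- function(n = 400, seed = 3) {
  cached(sprintf("noiseless_%d_%d", n, seed), generate_cohort(default_config(
    n_patients = n, seed = seed, perfect_senior = TRUE,
    rater_presence_agreement = 1, rater_grade_confusion = diag(4)
  )))
}

# a tiny readings table written by hand: 3 patients, readers R1/R2 (+SENIOR)
tiny_readings <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C"),
    reader_id  = c("R1", "R2", "SENIOR",
                   "R1", "R1", "R2", "SENIOR",
                   "R1", "R2", "SENIOR"),
    level      = c("T12", "T12", "T12",
                   "T8", "L1", "T8", "L1",
                   "NONE", "L2", "NONE"),
    grade      = c(2L, 2L, 2L,
                   1L, 2L, 1L, 3L,
                   0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}
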