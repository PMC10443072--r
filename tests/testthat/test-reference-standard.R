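reading <- function(pid, rid, levels = character(0), grades = integer(0)) {
  vertebral_reading(pid, rid, levels, grades)
}

test_that("disagreement flags follow the presence/grade/location definitions", {
  a <- reading("P1", "R1", "T12", 2L)
  expect_equal(detect_disagreement(a, reading("P1", "R2", "T12", 2L)),
               list(presence = FALSE, grade = FALSE, location = FALSE))
  # presence discordance implies location (and hence grade) discordance
  expect_equal(detect_disagreement(a, reading("P1", "R2")),
               list(presence = TRUE, grade = TRUE, location = TRUE))
  # same level, different grade: grade-only disagreement
  expect_equal(detect_disagreement(a, reading("P1", "R2", "T12", 3L)),
               list(presence = FALSE, grade = TRUE, location = FALSE))
  # same presence, different levels: location (and grade) disagreement
  expect_equal(detect_disagreement(a, reading("P1", "R2", "L1", 2L)),
               list(presence = FALSE, grade = TRUE, location = TRUE))
  # a level graded by only one reader is a location disagreement
  b <- reading("P1", "R2", c("T12", "L1"), c(2L, 1L))
  expect_true(detect_disagreement(a, b)$location)
  expect_error(detect_disagreement(a, reading("P2", "R2", "T12", 2L)),
               "different patients")
})

test_that("adjudication keeps agreed readings and defers to the senior otherwise", {
  a <- reading("P1", "R1", c("T8", "L1"), c(1L, 2L))
  b <- reading("P1", "R2", c("L1", "T8"), c(2L, 1L))   # same set, other order
  cons <- adjudicate(a, b, senior = NULL)
  expect_false(cons$adjudicated)
  expect_equal(cons$levels, a$levels)

  senior <- reading("P1", "SENIOR", "L1", 1L)
  cons2 <- adjudicate(a, reading("P1", "R2", "T8", 1L), senior)
  expect_true(cons2$adjudicated)
  expect_equal(cons2$levels, "L1")
  expect_equal(cons2$grades, 1L)

  # grade-only disagreement: consensus grade is the senior's grade
  s3 <- reading("P1", "SENIOR", "T12", 3L)
  cons3 <- adjudicate(reading("P1", "R1", "T12", 2L),
                      reading("P1", "R2", "T12", 1L), s3)
  expect_equal(cons3$grades, 3L)

  expect_error(adjudicate(a, reading("P1", "R2", "T8", 1L), senior = NULL),
               "patient P1")
})

test_that("patient summaries compute any/max/count and empty sets give grade 0", {
  s <- patient_summary(character(0), integer(0), "P0")
  expect_equal(s[c("any_vcf", "max_grade", "n_fractures")],
               list(any_vcf = FALSE, max_grade = 0L, n_fractures = 0L))
  s2 <- patient_summary(c("T12", "L1"), c(2L, 3L), "P1")
  expect_true(s2$any_vcf)
  expect_equal(s2$max_grade, 3L)
  expect_equal(s2$n_fractures, 2L)
  expect_equal(s2$per_level, c(T12 = 2L, L1 = 3L))
})

test_that("readings with NONE placeholders canonicalize to empty finding sets", {
  r <- vertebral_reading("P1", "R1", "NONE", 0L)
  expect_length(r$levels, 0)
  expect_error(vertebral_reading("P1", "R1", c("T12", "T12"), c(1L, 2L)),
               "more than one grade")
  expect_error(vertebral_reading("P1", "R1", "T13", 1L), "unknown vertebral")
})

test_that("build_reference adjudicates a readings table correctly", {
  ref <- build_reference(tiny_readings())
  expect_equal(attr(ref, "n_adjudicated"), 2L)  # patients B (grade) and C (presence)
  expect_equal(ref$patient_id, c("A", "B", "C"))
  # A: readers agree -> first reading
  expect_equal(ref$T12[1], 2L)
  expect_equal(ref$n_fractures[1], 1L)
  # B: readers disagree on L1 -> senior reading {L1:3} replaces everything
  expect_equal(ref$max_grade[2], 3L)
  expect_equal(ref$n_fractures[2], 1L)
  expect_equal(ref$T8[2], 0L)
  # C: presence disagreement, senior reports nothing
  expect_false(ref$any_vcf[3])
  expect_equal(ref$max_grade[3], 0L)

  # senior missing when needed names the patient
  broken <- tiny_readings()
  broken <- broken[!(broken$patient_id == "B" & broken$reader_id == "SENIOR"), ]
  expect_error(build_reference(broken), "patient B")
})

test_that("adjudicated reference equals generator truth for noiseless readers", {
  coh <- noiseless_cohort()
  ref <- build_reference(coh$readings)
  expect_equal(attr(ref, "n_adjudicated"), 0L)
  attr(ref, "n_adjudicated") <- NULL
  expect_identical(ref, truth_reference(coh))
})
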