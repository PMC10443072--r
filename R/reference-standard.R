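#' A single reader's vertebral reading for one patient
#'
#' Constructs the finding set one reader reports for one patient: zero or
#' more (vertebral level, Genant grade) pairs.  A `NONE`/0 placeholder row
#' (the on-disk encoding of an empty reading) is canonicalized away.
#'
#' @param patient_id,reader_id Identifiers.
#' @param levels Character vector of vertebral levels (subset of
#'   [spine_levels()], or `"NONE"` for an empty reading).
#' @param grades Integer vector of Genant grades 1-3, same length as
#'   `levels` (0 allowed only on `NONE` placeholder rows).
#' @return An object of class `vertebral_reading`.
#' @export
vertebral_reading <- function(patient_id, reader_id, levels = character(0),
                              grades = integer(0)) {
  if (length(levels) != length(grades))
    stopf("levels and grades must have equal length")
  keep <- !(levels == "NONE" | grades == 0L)
  levels <- as.character(levels[keep])
  grades <- as.integer(grades[keep])
  bad <- setdiff(levels, spine_levels())
  if (length(bad))
    stopf("unknown vertebral level(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(levels))
    stopf("reading for patient %s has more than one grade at a level", patient_id)
  if (length(grades) && (any(grades < 1L) || any(grades > 3L)))
    stopf("grades of reported fractures must be 1, 2 or 3")
  structure(list(patient_id = as.character(patient_id),
                 reader_id = as.character(reader_id),
                 levels = levels, grades = grades),
            class = "vertebral_reading")
}

#' @export
print.vertebral_reading <- function(x, ...) {
  cat(sprintf("Reading by %s for patient %s: %s\n", x$reader_id, x$patient_id,
              if (!length(x$levels)) "no VCF" else
                paste(sprintf("%s:%d", x$levels, x$grades), collapse = ", ")))
  invisible(x)
}

# Core flag computation on level/grade vectors.  The grade flag is true
# whenever the location flag is (a level graded by only one reader is both a
# location and a grade difference); presence disagreement implies location.
disagreement_flags <- function(lev_a, gr_a, lev_b, gr_b) {
  location <- !(length(lev_a) == length(lev_b) && setequal(lev_a, lev_b))
  presence <- (length(lev_a) > 0L) != (length(lev_b) > 0L)
  shared <- intersect(lev_a, lev_b)
  grade_diff <- length(shared) > 0L &&
    any(gr_a[match(shared, lev_a)] != gr_b[match(shared, lev_b)])
  list(presence = presence, grade = grade_diff || location, location = location)
}

#' Compare two readings of the same patient
#'
#' Flags the three kinds of reader disagreement that trigger adjudication:
#' presence (one reader sees at least one VCF, the other none), location
#' (differing level sets) and grade (a shared level graded differently, or
#' any location difference).
#'
#' @param a,b [vertebral_reading()] objects for the same patient.
#' @return A list with logical elements `presence`, `grade`, `location`.
#' @export
detect_disagreement <- function(a, b) {
  stopifnot(inherits(a, "vertebral_reading"), inherits(b, "vertebral_reading"))
  if (a$patient_id != b$patient_id)
    stopf("readings refer to different patients (%s vs %s)",
          a$patient_id, b$patient_id)
  disagreement_flags(a$levels, a$grades, b$levels, b$grades)
}

#' Adjudicate a pair of readings
#'
#' Reproduces the study's disagreement-resolution workflow: if the two
#' primary readings agree on presence, location and grade, the consensus is
#' the first reading; on any disagreement the senior reader's entire reading
#' becomes the final diagnosis.
#'
#' @param a,b Primary [vertebral_reading()]s for the same patient.
#' @param senior The senior reader's [vertebral_reading()], or `NULL` if
#'   unavailable (an error if adjudication turns out to be needed).
#' @return A list with elements `levels`, `grades` (the consensus finding
#'   set) and `adjudicated` (logical).
#' @export
adjudicate <- function(a, b, senior = NULL) {
  flags <- detect_disagreement(a, b)
  if (!flags$presence && !flags$grade && !flags$location)
    return(list(levels = a$levels, grades = a$grades, adjudicated = FALSE))
  if (is.null(senior))
    stopf("patient %s: readers disagree but no senior reading is available",
          a$patient_id)
  stopifnot(inherits(senior, "vertebral_reading"))
  if (senior$patient_id != a$patient_id)
    stopf("senior reading refers to a different patient (%s vs %s)",
          senior$patient_id, a$patient_id)
  list(levels = senior$levels, grades = senior$grades, adjudicated = TRUE)
}

#' Patient-level summary of a consensus finding set
#'
#' @param levels,grades The consensus finding set (parallel vectors).
#' @param patient_id Identifier carried into the summary.
#' @return A list: `patient_id`, `any_vcf`, `max_grade` (0 for an empty
#'   set), `n_fractures`, `per_level` (named integer vector of grades over
#'   the fractured levels).
#' @export
patient_summary <- function(levels, grades, patient_id = NA_character_) {
  list(patient_id = patient_id,
       any_vcf = length(levels) > 0L,
       max_grade = if (length(grades)) max(grades) else 0L,
       n_fractures = length(levels),
       per_level = stats::setNames(as.integer(grades), levels))
}

# Long findings (patient_id, level, grade) -> wide patient-level reference
# (one grade column per vertebral level).  patient_ids fixes row order and
# includes patients without findings.
findings_to_reference <- function(patient_ids, findings) {
  pats <- unique(patient_ids)
  lv <- spine_levels()
  m <- matrix(0L, nrow = length(pats), ncol = 17, dimnames = list(NULL, lv))
  if (nrow(findings)) {
    ri <- match(findings$patient_id, pats)
    ci <- match(findings$level, lv)
    if (anyNA(ri))
      stopf("findings contain unknown patient id(s): %s",
            paste(unique(findings$patient_id[is.na(ri)]), collapse = ", "))
    if (anyNA(ci))
      stopf("findings contain unknown level(s): %s",
            paste(unique(findings$level[is.na(ci)]), collapse = ", "))
    if (anyDuplicated(ri * 32L + ci))
      stopf("more than one grade at the same (patient, level)")
    m[cbind(ri, ci)] <- as.integer(findings$grade)
  }
  n_frac <- as.integer(rowSums(m > 0L))
  out <- data.frame(patient_id = pats,
                    any_vcf = n_frac > 0L,
                    max_grade = as.integer(do.call(pmax, as.data.frame(m))),
                    n_fractures = n_frac,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m))
}

#' Build the adjudicated reference standard from a readings table
#'
#' Applies the dual-reader adjudication workflow to every patient in a
#' readings table: the two primary readings are compared, and on any
#' presence/grade/location disagreement the senior reading (reader id
#' `SENIOR`) becomes the final diagnosis.
#'
#' @param readings Data frame with columns `patient_id`, `reader_id`,
#'   `level`, `grade` (one row per flagged vertebra; an empty reading is a
#'   `NONE`/0 row).  Each patient must carry exactly two primary readers;
#'   a `SENIOR` reading is required only for patients whose primaries
#'   disagree.
#' @return Data frame with one row per patient: `patient_id`, `any_vcf`,
#'   `max_grade`, `n_fractures` and one grade column per vertebral level.
#'   The number of adjudicated patients is attached as attribute
#'   `n_adjudicated`.
#' @export
build_reference <- function(readings) {
  need <- c("patient_id", "reader_id", "level", "grade")
  missing <- setdiff(need, names(readings))
  if (length(missing))
    stopf("readings table lacks column(s): %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(readings$level), c(spine_levels(), "NONE"))
  if (length(bad))
    stopf("readings table contains unknown level(s): %s",
          paste(bad, collapse = ", "))

  pats <- unique(readings$patient_id)
  rows <- split(seq_len(nrow(readings)),
                factor(readings$patient_id, levels = pats))
  real <- !(readings$level == "NONE" | readings$grade == 0L)

  cons_pid <- vector("list", length(pats))
  cons_lev <- vector("list", length(pats))
  cons_gr <- vector("list", length(pats))
  n_adj <- 0L
  for (i in seq_along(pats)) {
    r <- rows[[i]]
    rid <- readings$reader_id[r]
    prim <- setdiff(unique(rid), "SENIOR")
    if (length(prim) != 2L)
      stopf("patient %s: expected exactly 2 primary readers, found %d",
            pats[i], length(prim))
    ra <- r[rid == prim[1] & real[r]]
    rb <- r[rid == prim[2] & real[r]]
    lev_a <- readings$level[ra]; gr_a <- readings$grade[ra]
    lev_b <- readings$level[rb]; gr_b <- readings$grade[rb]
    if (anyDuplicated(lev_a) || anyDuplicated(lev_b))
      stopf("patient %s: a reader reports more than one grade at a level", pats[i])
    flags <- disagreement_flags(lev_a, gr_a, lev_b, gr_b)
    if (flags$presence || flags$grade || flags$location) {
      if (!any(rid == "SENIOR"))
        stopf("patient %s: readers disagree but no senior reading is available",
              pats[i])
      rs <- r[rid == "SENIOR" & real[r]]
      lev_c <- readings$level[rs]; gr_c <- readings$grade[rs]
      n_adj <- n_adj + 1L
    } else {
      lev_c <- lev_a; gr_c <- gr_a
    }
    if (length(lev_c)) {
      cons_pid[[i]] <- rep(pats[i], length(lev_c))
      cons_lev[[i]] <- lev_c
      cons_gr[[i]] <- gr_c
    }
  }
  consensus <- data.frame(
    patient_id = unlist(cons_pid) %||% character(0),
    level = unlist(cons_lev) %||% character(0),
    grade = as.integer(unlist(cons_gr) %||% integer(0)),
    stringsAsFactors = FALSE
  )
  out <- findings_to_reference(pats, consensus)
  attr(out, "n_adjudicated") <- n_adj
  out
}
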