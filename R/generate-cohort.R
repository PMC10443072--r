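#' Generate a synthetic validation cohort
#'
#' Simulates the full data-generating process the validation analysis
#' assumes: a latent fracture truth per patient (levels and Genant grades),
#' two primary neuroradiologist readings drawn from a pool of three readers,
#' a senior (adjudicating) reading, a patient-level detector result
#' (positive / negative / non-evaluable), and demographics.
#'
#' Each patient is simulated from its own RNG substream derived from
#' `config$seed`, so the same patient index yields the same record
#' regardless of `n_patients`.  The detector operates at the patient level
#' only: its hit probability is keyed to the patient's most severe fracture
#' grade, fracture-free patients trigger false positives at
#' `detector_fpr`, and non-evaluable status is (by default) independent of
#' fracture status.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `vcf_cohort`: a list with elements
#'   `truth` (data frame: patient_id, level, grade; one row per true
#'   fracture), `readings` (patient_id, reader_id, level, grade; reader ids
#'   `R1`-`R3` for the two primary readers and `SENIOR` for the adjudicator;
#'   patients with no findings carry a single `NONE`/0 row), `index`
#'   (patient_id, result), `demographics`
#'   (patient_id, age_years, sex, region, prior_vcf), and `config`.
#' @examples
#' coh <- generate_cohort(default_config(n_patients = 200))
#' table(coh$index$result)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("'config' must be a cohort_config object")
  validate_config(config)

  n <- config$n_patients
  levels17 <- spine_levels()
  # cumulative rows of the confusion matrices, for inverse-CDF grade draws
  cum_rater  <- t(apply(config$rater_grade_confusion,  1, cumsum))[, 1:3, drop = FALSE]
  cum_senior <- t(apply(config$senior_grade_confusion, 1, cumsum))[, 1:3, drop = FALSE]
  gm_cum <- cumsum(config$grade_mix)
  # non-evaluable probability for fractured patients via the odds multiplier
  ne <- config$nonevaluable_rate
  ne_odds <- config$nonevaluable_or_fractured * ne / (1 - ne)
  ne_frac <- ne_odds / (1 + ne_odds)

  read_levels <- function(gvec, agreement, cum) {
    # one reader's reported grade per level, vectorised over the 17 levels:
    # inverse-CDF draw from the confusion row of each level's true grade,
    # with true fractures first subject to a detection coin
    u_detect <- stats::runif(17)
    u_grade <- stats::runif(17)
    reported <- (u_grade > cum[gvec + 1L, 1L]) + (u_grade > cum[gvec + 1L, 2L]) +
      (u_grade > cum[gvec + 1L, 3L])
    reported[gvec > 0L & u_detect > agreement] <- 0L
    as.integer(reported)
  }

  tr_pid <- vector("list", n); tr_lev <- vector("list", n); tr_gr <- vector("list", n)
  rd_pid <- vector("list", n); rd_rid <- vector("list", n)
  rd_lev <- vector("list", n); rd_gr <- vector("list", n)
  idx_res <- character(n)
  age <- integer(n); sex <- character(n); region <- character(n); prior <- integer(n)
  pid <- sprintf("P%05d", seq_len(n))
  age_lo <- c(50L, 61L, 71L, 81L, 91L)
  age_hi <- c(60L, 70L, 80L, 90L, 102L)
  regions <- c("chest", "abdomen_pelvis", "both")

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    g <- integer(17)

    fractured <- stats::runif(1) < config$prevalence_any
    if (fractured) {
      max_grade <- 1L + findInterval(stats::runif(1), gm_cum[1:2])
      multi <- stats::runif(1) < config$multi_fracture_prob
      count <- if (multi) min(17L, 2L + stats::rgeom(1, config$multi_extra_geom)) else 1L
      levs <- sample.int(17L, count, prob = config$level_weights)
      g[levs[1]] <- max_grade
      if (count > 1L) {
        w <- config$grade_mix[seq_len(max_grade)]
        g[levs[-1]] <- sample.int(max_grade, count - 1L, replace = TRUE, prob = w)
      }
      tr_pid[[i]] <- rep(pid[i], count)
      ord <- order(levs)
      tr_lev[[i]] <- levels17[levs[ord]]
      tr_gr[[i]] <- g[levs[ord]]
    }

    readers <- paste0("R", sort(sample.int(3L, 2L)))
    rep1 <- read_levels(g, config$rater_presence_agreement, cum_rater)
    rep2 <- read_levels(g, config$rater_presence_agreement, cum_rater)
    rep3 <- if (config$perfect_senior) g
            else read_levels(g, config$senior_presence_agreement, cum_senior)
    ids <- c(readers, "SENIOR")
    reps <- list(rep1, rep2, rep3)
    p_l <- character(0); p_r <- character(0); p_g <- integer(0)
    for (k in 1:3) {
      hit <- which(reps[[k]] > 0L)
      if (length(hit)) {
        p_l <- c(p_l, levels17[hit]); p_g <- c(p_g, reps[[k]][hit])
        p_r <- c(p_r, rep(ids[k], length(hit)))
      } else {
        p_l <- c(p_l, "NONE"); p_g <- c(p_g, 0L); p_r <- c(p_r, ids[k])
      }
    }
    rd_pid[[i]] <- rep(pid[i], length(p_l))
    rd_rid[[i]] <- p_r; rd_lev[[i]] <- p_l; rd_gr[[i]] <- p_g

    u_ne <- stats::runif(1)
    u_pos <- stats::runif(1)
    if (u_ne < (if (fractured) ne_frac else ne)) {
      idx_res[i] <- "non_evaluable"
    } else if (fractured) {
      idx_res[i] <- if (u_pos < config$detector_sens_by_grade[max(g)])
        "positive" else "negative"
    } else {
      idx_res[i] <- if (u_pos < config$detector_fpr) "positive" else "negative"
    }

    sex[i] <- if (stats::runif(1) < config$female_fraction) "F" else "M"
    bin <- findInterval(stats::runif(1), cumsum(config$age_bins)[1:4]) + 1L
    age[i] <- age_lo[bin] +
      as.integer(floor(stats::runif(1) * (age_hi[bin] - age_lo[bin] + 1L)))
    region[i] <- regions[findInterval(stats::runif(1), cumsum(config$region_weights)[1:2]) + 1L]
    p_prior <- if (fractured) config$prior_vcf_prob_fractured
               else config$prior_vcf_prob_unfractured
    prior[i] <- as.integer(stats::runif(1) < p_prior)
  }

  cohort <- list(
    truth = data.frame(
      patient_id = unlist(tr_pid) %||% character(0),
      level = unlist(tr_lev) %||% character(0),
      grade = as.integer(unlist(tr_gr) %||% integer(0)),
      stringsAsFactors = FALSE
    ),
    readings = data.frame(
      patient_id = unlist(rd_pid) %||% character(0),
      reader_id = unlist(rd_rid) %||% character(0),
      level = unlist(rd_lev) %||% character(0),
      grade = as.integer(unlist(rd_gr) %||% integer(0)),
      stringsAsFactors = FALSE
    ),
    index = data.frame(patient_id = pid, result = idx_res,
                       stringsAsFactors = FALSE),
    demographics = data.frame(patient_id = pid, age_years = age, sex = sex,
                              region = region, prior_vcf = prior,
                              stringsAsFactors = FALSE),
    config = config
  )
  class(cohort) <- "vcf_cohort"
  cohort
}

#' @export
print.vcf_cohort <- function(x, ...) {
  n <- nrow(x$index)
  nf <- length(unique(x$truth$patient_id))
  cat(sprintf("Synthetic VCF cohort: %d patients, %d with >=1 true fracture (%d fractures)\n",
              n, nf, nrow(x$truth)))
  print(table(x$index$result))
  invisible(x)
}

#' Patient-level truth summary of a synthetic cohort
#'
#' Collapses the generator's fracture truth to the same patient-level layout
#' produced by [build_reference()]: any-VCF flag, maximum grade, fracture
#' count and one grade column per vertebral level.  Used to check that the
#' adjudicated reference recovers the truth when readers are noiseless.
#'
#' @param cohort A `vcf_cohort`.
#' @return Data frame with one row per patient.
#' @export
truth_reference <- function(cohort) {
  stopifnot(inherits(cohort, "vcf_cohort"))
  findings_to_reference(cohort$index$patient_id, cohort$truth)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `readings.csv`, `index.csv` and `demographics.csv` (the three input
#' tables of the validation pipeline) plus `truth.csv` (the synthetic
#' generator's latent truth, for parameter-recovery checks).
#'
#' @param cohort A `vcf_cohort`.
#' @param dir Output directory (created if absent).
#' @param include_truth Write `truth.csv` as well (default `TRUE`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, include_truth = TRUE) {
  stopifnot(inherits(cohort, "vcf_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory '%s'", dir)
  paths <- c(
    readings = file.path(dir, "readings.csv"),
    index = file.path(dir, "index.csv"),
    demographics = file.path(dir, "demographics.csv")
  )
  utils::write.csv(cohort$readings, paths["readings"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$index, paths["index"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$demographics, paths["demographics"], row.names = FALSE, quote = FALSE)
  if (include_truth) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read cohort tables back from CSV files
#'
#' Inverse of [write_cohort()]: reads `readings.csv`, `index.csv`,
#' `demographics.csv` and, when present, `truth.csv`.
#'
#' @param dir Directory containing the files.
#' @return A list with elements `readings`, `index`, `demographics` and
#'   (possibly `NULL`) `truth`.
#' @export
read_cohort <- function(dir) {
  req <- file.path(dir, c("readings.csv", "index.csv", "demographics.csv"))
  missing <- req[!file.exists(req)]
  if (length(missing))
    stopf("missing cohort file(s): %s", paste(basename(missing), collapse = ", "))
  readings <- utils::read.csv(req[1], colClasses = c(
    patient_id = "character", reader_id = "character",
    level = "character", grade = "integer"))
  index <- utils::read.csv(req[2], colClasses = c(
    patient_id = "character", result = "character"))
  bad <- setdiff(unique(index$result), c("positive", "negative", "non_evaluable"))
  if (length(bad))
    stopf("index.csv: invalid result value(s): %s", paste(bad, collapse = ", "))
  demographics <- utils::read.csv(req[3], colClasses = c(
    patient_id = "character", age_years = "integer", sex = "character",
    region = "character", prior_vcf = "integer"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, colClasses = c(
      patient_id = "character", level = "character", grade = "integer"))
  }
  list(readings = readings, index = index, demographics = demographics,
       truth = truth)
}
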