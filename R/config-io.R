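# Cohort configuration file round-trip (YAML key/value document mirroring
# cohort_config; a CLI-style --seed override is a plain argument here).

#' Write / read a cohort configuration file
#'
#' Serializes a [cohort_config()] to a YAML document (matrices stored
#' row-wise) and reads it back.  `read_config()` re-validates, so a
#' hand-edited file with inconsistent probabilities is rejected.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @param seed Optional seed override applied on read.
#' @return `read_config()` returns a `cohort_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$rater_grade_confusion <- apply(config$rater_grade_confusion, 1, c,
                                   simplify = FALSE)
  x$senior_grade_confusion <- apply(config$senior_grade_confusion, 1, c,
                                    simplify = FALSE)
  x$level_weights <- as.numeric(config$level_weights)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, seed = NULL) {
  x <- yaml::read_yaml(path)
  x$rater_grade_confusion <- do.call(rbind, x$rater_grade_confusion)
  x$senior_grade_confusion <- do.call(rbind, x$senior_grade_confusion)
  x$level_weights <- stats::setNames(as.numeric(x$level_weights),
                                     spine_levels())
  if (!is.null(seed)) x$seed <- as.integer(seed)
  do.call(cohort_config, x)
}
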