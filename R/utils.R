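# Internal helpers shared across modules.

#' Spinal levels covered by the analysis
#'
#' The 17 vertebral levels (T1--T12, L1--L5) at which fractures are graded,
#' in anatomical order.
#'
#' @return Character vector of length 17.
#' @export
spine_levels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

# Round half away from zero at a fixed number of decimals (the convention
# used for comparisons against printed values; base round() is half-to-even).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a per-patient RNG substream seed from a root seed, so that cohorts
# of different sizes share the realisations of their common patients.
patient_seed <- function(root_seed, i) {
  (as.numeric(root_seed) %% 2147483647 + i * 48271) %% 2147483647
}

# Tiny FNV-1a hash of a character serialisation, for report provenance.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
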