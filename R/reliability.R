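#' @name reliability
#' @title Inter-rater reliability via variance components
#'
#' @description
#' The reliability analysis treats each (patient, rater) initial rating as
#' one row of a linear mixed model
#' \deqn{y_{ij} = \mu + r_j + b_i + e_{ij},}
#' with a fixed effect \eqn{r_j} per rater (one rater absorbed into the
#' intercept), a random intercept \eqn{b_i \sim N(0, \sigma^2_b)} per
#' patient, and residual \eqn{e_{ij} \sim N(0, \sigma^2_e)}.  The
#' intraclass correlation coefficient is the ratio of between-subject
#' variance to total variance,
#' \eqn{ICC = \sigma^2_b / (\sigma^2_b + \sigma^2_e)}.
#'
#' The fit is restricted maximum likelihood, profiled to a one-dimensional
#' search over \eqn{\theta = \sigma^2_b/\sigma^2_e} using the block-diagonal
#' structure of the marginal covariance (ratings are independent across
#' patients).  All per-patient information is reduced to sufficient
#' statistics first, so a fit costs O(patients) once and O(1) per likelihood
#' evaluation --- fast enough to sit inside bootstrap and jackknife loops.
NULL

# ---- sufficient statistics -------------------------------------------------

# Reduce a long ratings table to per-patient sufficient statistics.
# Column 1 of the implicit design is the intercept; raters 2..p enter as
# dummy columns (rater 1, first level alphabetically, is the reference).
rs_build <- function(patient, rater, y) {
  if (anyNA(y) || any(!is.finite(y))) stopf("outcomes must be finite")
  pf <- factor(patient, levels = unique(patient))
  gi <- as.integer(pf)
  n <- nlevels(pf)
  rf <- factor(rater)
  p_dummies <- max(nlevels(rf) - 1L, 0L)
  k <- tabulate(gi, n)
  ys <- as.numeric(rowsum(y, gi))
  yy <- as.numeric(rowsum(y * y, gi))
  if (p_dummies > 0L) {
    ind <- outer(as.integer(rf), 2L:(p_dummies + 1L), `==`) + 0
    D <- rowsum(ind, gi)
    V <- rowsum(ind * y, gi)
  } else {
    D <- matrix(0, n, 0)
    V <- matrix(0, n, 0)
  }
  list(n = n, k = k, ys = ys, yy = yy, D = D, V = V,
       rater_levels = levels(rf), patients = levels(pf))
}

# REML fit on a subset of patients (with multiplicity, for bootstrap
# resamples).  Returns variance components, rater effects and the ICC.
rs_fit <- function(ss, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(ss$n)
  k <- ss$k[idx]; ys <- ss$ys[idx]; yy <- ss$yy[idx]
  D <- ss$D[idx, , drop = FALSE]; V <- ss$V[idx, , drop = FALSE]
  n <- length(idx); N <- sum(k)
  # center the outcome (add the mean back to the intercept at the end):
  # keeps the quadratic forms well conditioned, so the ICC is invariant to
  # location shifts at machine precision
  ybar <- sum(ys) / N
  yy <- yy - 2 * ybar * ys + k * ybar^2
  V <- V - ybar * D
  ys <- ys - k * ybar
  Ty <- sum(ys); Tyy <- sum(yy)
  Td <- colSums(D); Tv <- colSums(V)
  keep <- Td > 0                       # raters absent from this subset drop out
  D <- D[, keep, drop = FALSE]; V <- V[, keep, drop = FALSE]
  Td <- Td[keep]; Tv <- Tv[keep]
  p <- 1L + ncol(D)

  tss <- Tyy                       # y is centered, so this is the total SS
  if (tss <= 1e-12 * max(1, ybar^2)) {
    # all outcomes identical: both variances degenerate
    eff <- stats::setNames(c(ybar, rep(0, ncol(D))),
                           c("(intercept)", ss$rater_levels[-1][keep]))
    return(list(sigma2_subject = 0, sigma2_resid = 0, icc = 1,
                rater_effects = eff, degenerate = TRUE, theta = Inf,
                n_patients = n, n_ratings = N))
  }

  XtX <- diag(c(N, Td), nrow = p)
  XtX[1, -1] <- Td; XtX[-1, 1] <- Td
  Xty <- c(Ty, Tv)

  ks <- sort(unique(k))
  grp <- lapply(ks, function(kk) {
    sel <- k == kk
    S <- cbind(kk, D[sel, , drop = FALSE])
    list(kk = kk, n = sum(sel), M = crossprod(S),
         w = as.numeric(crossprod(S, ys[sel])), q = sum(ys[sel]^2))
  })

  assemble <- function(theta) {
    A <- XtX; u <- Xty; yWy <- Tyy; ldW <- 0
    for (g in grp) {
      cg <- theta / (1 + g$kk * theta)
      A <- A - cg * g$M
      u <- u - cg * g$w
      yWy <- yWy - cg * g$q
      ldW <- ldW + g$n * log1p(g$kk * theta)
    }
    list(A = A, u = u, yWy = yWy, ldW = ldW)
  }
  objective <- function(t) {
    q <- assemble(exp(t))
    ch <- tryCatch(chol(q$A), error = function(e) NULL)
    if (is.null(ch)) return(1e30)
    beta <- backsolve(ch, forwardsolve(t(ch), q$u))
    rWr <- q$yWy - sum(beta * q$u)
    if (!is.finite(rWr) || rWr <= 0) rWr <- 1e-280
    (N - p) * log(rWr) + q$ldW + 2 * sum(log(diag(ch)))
  }

  lower <- -30; upper <- 15
  opt <- stats::optimize(objective, c(lower, upper), tol = 1e-8)
  t_hat <- opt$minimum
  # Brent never lands exactly on a bound; compare against the bounds too
  if (objective(lower) <= opt$objective) t_hat <- lower
  if (objective(upper) <= opt$objective) t_hat <- upper
  if (t_hat > lower + 1e-6 && t_hat < upper - 1e-6) {
    # polish the interior optimum: Brent stops near sqrt(machine eps); a few
    # finite-difference Newton steps reach the stationary point itself
    h <- 1e-4
    for (it in 1:6) {
      f0 <- objective(t_hat)
      fp <- objective(t_hat + h); fm <- objective(t_hat - h)
      g <- (fp - fm) / (2 * h)
      hess <- (fp - 2 * f0 + fm) / h^2
      if (!is.finite(g) || !is.finite(hess) || hess <= 0) break
      step <- g / hess
      t_new <- min(max(t_hat - step, lower), upper)
      if (abs(t_new - t_hat) < 1e-12) { t_hat <- t_new; break }
      t_hat <- t_new
    }
  }
  theta <- exp(t_hat)

  q <- assemble(theta)
  beta <- solve(q$A, q$u)
  rWr <- q$yWy - sum(beta * q$u)
  beta[1] <- beta[1] + ybar        # undo the centering in the intercept
  eff <- stats::setNames(beta, c("(intercept)", ss$rater_levels[-1][keep]))

  if (t_hat >= upper - 1e-6) {
    # zero within-patient variance (e.g. noiseless raters): ICC degenerates to 1
    return(list(sigma2_subject = tss / max(N - 1, 1), sigma2_resid = 0,
                icc = 1, rater_effects = eff, degenerate = TRUE,
                theta = Inf, n_patients = n, n_ratings = N))
  }
  sigma2_e <- max(rWr, 0) / (N - p)
  sigma2_b <- theta * sigma2_e
  if (t_hat <= lower + 1e-6) { sigma2_b <- 0; theta <- 0 }
  icc <- if (sigma2_b + sigma2_e > 0) sigma2_b / (sigma2_b + sigma2_e) else 1
  list(sigma2_subject = sigma2_b, sigma2_resid = sigma2_e,
       icc = min(max(icc, 0), 1), rater_effects = eff, degenerate = FALSE,
       theta = theta, n_patients = n, n_ratings = N)
}

check_ratings <- function(ratings) {
  need <- c("patient_id", "rater_id", "outcome")
  missing <- setdiff(need, names(ratings))
  if (length(missing))
    stopf("ratings table lacks column(s): %s", paste(missing, collapse = ", "))
  if (length(unique(ratings$patient_id)) < 2)
    stopf("at least 2 patients are required")
  invisible(ratings)
}

#' Fit the variance-components reliability model
#'
#' REML estimates of the between-patient and residual variances (rater as a
#' fixed effect) from a long ratings table, and the implied intraclass
#' correlation coefficient.  See [reliability] for the model.  Negative
#' variance estimates are truncated to zero; if the within-patient variance
#' degenerates to zero (e.g. raters always agree) the ICC is returned as 1
#' with `degenerate = TRUE`.
#'
#' @param ratings Data frame with columns `patient_id`, `rater_id`,
#'   `outcome` (one row per initial rating; in the study design each patient
#'   is rated by 2 of a pool of 3 raters, but any block size is accepted).
#' @return An object of class `icc_estimate`: `sigma2_subject`,
#'   `sigma2_resid`, `icc`, `rater_effects` (intercept and per-rater
#'   offsets), `degenerate`, `n_patients`, `n_ratings`.
#' @examples
#' r <- simulate_ratings(200, sigma2_subject = 1, sigma2_resid = 3 / 7, seed = 1)
#' fit_variance_components(r)$icc     # close to 0.70
#' @export
fit_variance_components <- function(ratings) {
  check_ratings(ratings)
  ss <- rs_build(ratings$patient_id, ratings$rater_id, ratings$outcome)
  out <- rs_fit(ss)
  class(out) <- "icc_estimate"
  out
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC = %.4f  (sigma2_subject = %.4f, sigma2_resid = %.4f%s)\n",
              x$icc, x$sigma2_subject, x$sigma2_resid,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  if (!is.null(x$ci_low))
    cat(sprintf("%.0f%% BCa CI: %.4f-%.4f  (%d bootstrap samples, seed %d)\n",
                100 * (x$level %||% 0.95), x$ci_low, x$ci_high,
                x$n_boot, x$seed))
  invisible(x)
}

# ---- BCa bootstrap ---------------------------------------------------------

# Rebuild a long ratings table for a patient resample; duplicated patients
# become distinct blocks.
resample_ratings <- function(ratings, rows_by_patient, idx) {
  rows <- rows_by_patient[idx]
  nrows <- lengths(rows)
  data.frame(
    patient_id = rep(seq_along(idx), nrows),
    rater_id = ratings$rater_id[unlist(rows, use.names = FALSE)],
    outcome = ratings$outcome[unlist(rows, use.names = FALSE)],
    stringsAsFactors = FALSE
  )
}

#' Bias-corrected accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric BCa interval for a statistic of a ratings table.  The
#' resampling unit is the patient: both of a patient's ratings travel
#' together, and rater identities are never resampled.  The bias-correction
#' constant `z0` comes from the fraction of bootstrap statistics below the
#' point estimate; the acceleration constant from the jackknife-over-patients
#' skewness formula.
#'
#' @param ratings Long ratings table (`patient_id`, `rater_id`, `outcome`).
#' @param statistic Function mapping such a table to a scalar, or `NULL`
#'   (the default) for the ICC of [fit_variance_components()], computed via
#'   a fast sufficient-statistic path.
#' @param n_boot Number of bootstrap samples (>= 200; the analysis default
#'   is 1000).
#' @param seed Integer seed making the interval reproducible.
#' @param level Confidence level.
#' @return A list: `ci_low`, `ci_high`, `point`, `z0`, `accel`, `n_boot`,
#'   `seed`, `level`, `n_failed` (bootstrap evaluations that errored; more
#'   than 5% aborts).
#' @export
bca_ci <- function(ratings, statistic = NULL, n_boot = 1000, seed = 1,
                   level = 0.95) {
  check_ratings(ratings)
  if (n_boot < 200) stopf("n_boot must be at least 200")
  fast <- is.null(statistic)
  pf <- factor(ratings$patient_id, levels = unique(ratings$patient_id))
  n <- nlevels(pf)

  if (fast) {
    ss <- rs_build(ratings$patient_id, ratings$rater_id, ratings$outcome)
    eval_stat <- function(idx) rs_fit(ss, idx)$icc
  } else {
    rows_by_patient <- split(seq_len(nrow(ratings)), pf)
    eval_stat <- function(idx)
      statistic(resample_ratings(ratings, rows_by_patient, idx))
  }

  point <- eval_stat(seq_len(n))
  if (!is.finite(point)) stopf("statistic is not finite on the full data")

  set.seed(seed)
  t_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    t_boot[b] <- tryCatch(eval_stat(idx), error = function(e) NA_real_)
  }
  n_failed <- sum(!is.finite(t_boot))
  if (n_failed > 0.05 * n_boot)
    stopf("statistic failed on %d of %d bootstrap resamples (> 5%%)",
          n_failed, n_boot)
  t_boot <- t_boot[is.finite(t_boot)]
  B <- length(t_boot)

  if (max(t_boot) - min(t_boot) < 1e-14 && abs(t_boot[1] - point) < 1e-14) {
    out <- list(ci_low = point, ci_high = point, point = point, z0 = 0,
                accel = 0, n_boot = n_boot, seed = seed, level = level,
                n_failed = n_failed)
    return(out)
  }

  prop <- (sum(t_boot < point) + 0.5 * sum(t_boot == point)) / B
  prop <- min(max(prop, 0.5 / B), 1 - 0.5 / B)
  z0 <- stats::qnorm(prop)

  jack <- vapply(seq_len(n), function(i)
    tryCatch(eval_stat(seq_len(n)[-i]), error = function(e) NA_real_),
    numeric(1))
  jack <- jack[is.finite(jack)]
  dev <- mean(jack) - jack
  denom <- sum(dev^2)^1.5
  accel <- if (denom > 0) sum(dev^3) / (6 * denom) else 0

  zq <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  ci <- stats::quantile(t_boot, probs = adj, names = FALSE, type = 6)
  list(ci_low = min(ci[1], point), ci_high = max(ci[2], point),
       point = point, z0 = z0, accel = accel, n_boot = n_boot, seed = seed,
       level = level, n_failed = n_failed)
}

# ---- outcome construction and the three-ICC suite --------------------------

#' Per-rating reliability outcomes from a readings table
#'
#' Collapses the primary readers' initial readings (senior rows excluded) to
#' one row per (patient, rater) with the three reliability outcomes:
#' `presence` (0/1, at least one VCF reported), `severity` (Genant grade of
#' the most severe reported VCF, 0 if none) and `count` (number of reported
#' VCFs).
#'
#' @param readings Readings table as in [build_reference()].
#' @return Data frame: `patient_id`, `rater_id`, `presence`, `severity`,
#'   `count`.
#' @export
reliability_outcomes <- function(readings) {
  prim <- readings[readings$reader_id != "SENIOR", , drop = FALSE]
  if (!nrow(prim)) stopf("no primary readings found")
  key <- paste(prim$patient_id, prim$reader_id, sep = "\r")
  kf <- factor(key, levels = unique(key))
  gi <- as.integer(kf)
  real <- !(prim$level == "NONE" | prim$grade == 0L)
  nk <- nlevels(kf)
  count <- as.integer(rowsum(real + 0L, gi))
  severity <- integer(nk)
  if (any(real)) {
    # max grade per group: sort by (group, grade) and take each group's last row
    g <- ifelse(real, as.integer(prim$grade), 0L)
    o <- order(gi, g)
    last <- !duplicated(gi[o], fromLast = TRUE)
    severity[gi[o][last]] <- g[o][last]
  }
  first <- !duplicated(gi)
  data.frame(patient_id = prim$patient_id[first],
             rater_id = prim$reader_id[first],
             presence = as.integer(count > 0L),
             severity = as.integer(severity),
             count = count,
             stringsAsFactors = FALSE)
}

#' Inter-rater reliability suite: presence, severity, count
#'
#' Runs the variance-components ICC with BCa bootstrap interval on the three
#' outcomes of the reliability analysis: presence of at least one VCF,
#' severity of the most severe VCF, and number of VCFs, each computed from
#' the primary readers' initial (pre-adjudication) readings and treated as a
#' continuous outcome.
#'
#' @param readings Readings table as in [build_reference()].
#' @param n_boot Bootstrap samples per outcome (default 1000).
#' @param seed Root seed; outcome o uses `seed + o - 1`.
#' @param level Confidence level.
#' @return A list of three `icc_estimate` objects named `presence`,
#'   `severity`, `count`, each with BCa fields attached; the summary data
#'   frame is available via [reliability_table()].
#' @export
icc_suite <- function(readings, n_boot = 1000, seed = 1, level = 0.95) {
  outc <- reliability_outcomes(readings)
  res <- list()
  for (o in seq_along(c("presence", "severity", "count"))) {
    nm <- c("presence", "severity", "count")[o]
    ratings <- data.frame(patient_id = outc$patient_id,
                          rater_id = outc$rater_id,
                          outcome = as.numeric(outc[[nm]]),
                          stringsAsFactors = FALSE)
    est <- fit_variance_components(ratings)
    ci <- bca_ci(ratings, statistic = NULL, n_boot = n_boot,
                 seed = seed + o - 1L, level = level)
    est$ci_low <- ci$ci_low; est$ci_high <- ci$ci_high
    est$z0 <- ci$z0; est$accel <- ci$accel
    est$n_boot <- n_boot; est$seed <- seed + o - 1L; est$level <- level
    res[[nm]] <- est
  }
  res
}

#' @rdname icc_suite
#' @param suite The list returned by [icc_suite()].
#' @return `reliability_table()`: data frame with one row per outcome:
#'   `outcome`, `sigma2_subject`, `sigma2_resid`, `icc`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`.
#' @export
reliability_table <- function(suite) {
  do.call(rbind, lapply(names(suite), function(nm) {
    e <- suite[[nm]]
    data.frame(outcome = nm, sigma2_subject = e$sigma2_subject,
               sigma2_resid = e$sigma2_resid, icc = e$icc,
               ci_low = e$ci_low %||% NA_real_,
               ci_high = e$ci_high %||% NA_real_,
               n_boot = e$n_boot %||% NA_integer_,
               seed = e$seed %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

# ---- ratings simulator -----------------------------------------------------

#' Simulate ratings from the reliability model
#'
#' Draws ratings from the generative model of [reliability]:
#' `y = mu + rater effect + patient effect + noise`, with the study's
#' two-of-three-raters design (each patient rated by a random pair from a
#' pool of 3) or a balanced complete design.
#'
#' @param n_patients Number of patients.
#' @param sigma2_subject,sigma2_resid True variance components; the implied
#'   ICC is `sigma2_subject / (sigma2_subject + sigma2_resid)`.
#' @param mu Grand mean.
#' @param rater_effects Numeric vector of fixed rater offsets (its length
#'   sets the rater pool size).
#' @param raters_per_patient Ratings per patient (default 2); use the pool
#'   size for a balanced complete design.
#' @param seed Integer seed.
#' @return Long ratings data frame (`patient_id`, `rater_id`, `outcome`).
#' @export
simulate_ratings <- function(n_patients, sigma2_subject = 1,
                             sigma2_resid = 3 / 7, mu = 0,
                             rater_effects = c(0, 0.1, -0.1),
                             raters_per_patient = 2, seed = 1) {
  n_raters <- length(rater_effects)
  if (raters_per_patient > n_raters)
    stopf("raters_per_patient cannot exceed the rater pool size")
  set.seed(seed)
  b <- stats::rnorm(n_patients, 0, sqrt(sigma2_subject))
  pid <- sprintf("P%05d", seq_len(n_patients))
  who <- matrix(0L, n_patients, raters_per_patient)
  for (i in seq_len(n_patients))
    who[i, ] <- sort(sample.int(n_raters, raters_per_patient))
  patient <- rep(pid, each = raters_per_patient)
  rater_idx <- as.integer(t(who))
  y <- mu + rater_effects[rater_idx] + rep(b, each = raters_per_patient) +
    stats::rnorm(length(rater_idx), 0, sqrt(sigma2_resid))
  data.frame(patient_id = patient,
             rater_id = paste0("R", rater_idx),
             outcome = y, stringsAsFactors = FALSE)
}
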