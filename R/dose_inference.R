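#' Invert a yield curve to a dose
#'
#' Solves `y = c + alpha * D + beta * D^2` for `D`. With `beta > 0` the
#' positive root is `D = (-alpha + sqrt(alpha^2 + 4 * beta * (y - c))) /
#' (2 * beta)`; with `beta = 0` the curve is linear. Yields at or below the
#' background `c` map to dose 0: negative doses are physically meaningless.
#'
#' @param curve An [lq_curve()] object.
#' @param observed_yield Observed MN per BN cell, vectorised.
#' @return Dose(s) in Gy.
#' @examples
#' invert_dose(published_curve("fully-automated"), 0.235)
#' @export
invert_dose <- function(curve, observed_yield) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(!is.finite(observed_yield))) abort("observed yield must be finite")
  p <- curve$coefficients
  cc <- p[["c"]]; a <- p[["alpha"]]; b <- p[["beta"]]
  if (a == 0 && b == 0) abort("curve is flat (alpha = beta = 0): not invertible")
  excess <- observed_yield - cc
  if (b > 0) {
    d <- (-a + sqrt(pmax(a^2 + 4 * b * excess, 0))) / (2 * b)
  } else {
    d <- excess / a
  }
  pmax(d, 0)
}

#' Assign a triage class to a dose
#'
#' Binary triage classification at a clinical cutoff (default 1.5 Gy, the
#' conventional threshold for likely acute radiation syndrome). The cutoff
#' itself is classified as the low ("<=") category.
#'
#' @param dose Point dose estimate(s) in Gy.
#' @param cutoff Cutoff in Gy.
#' @return Character vector, `"<=1.5"`-style labels built from `cutoff`.
#' @export
classify_triage <- function(dose, cutoff = 1.5) {
  ifelse(dose > cutoff, paste0(">", cutoff), paste0("<=", cutoff))
}

# Exact (Garwood) or normal-approximation 95% Poisson limits on a count.
poisson_limits <- function(m, conf = 0.95, method = c("exact", "approx")) {
  method <- match.arg(method)
  a <- (1 - conf) / 2
  if (method == "exact") {
    lower <- if (m == 0) 0 else qchisq(a, 2 * m) / 2
    upper <- qchisq(1 - a, 2 * m + 2) / 2
  } else {
    z <- qnorm(1 - a)
    lower <- max(m - z * sqrt(m), 0)
    upper <- m + z * sqrt(m)
  }
  c(lower = lower, upper = upper)
}

# Merged-error dose CI by the curve-crossing construction: Poisson limits on
# the observed count give yield limits; the curve band y(D) +/- z * se(D)
# is intersected with them by root-finding.
dose_ci_single <- function(curve, n_mn, n_bn, conf = 0.95, d_max = 10,
                           method = c("exact", "approx")) {
  if (n_bn <= 0) abort("n_bn must be positive")
  lim <- poisson_limits(n_mn, conf = conf, method = method)
  y_l <- lim[["lower"]] / n_bn
  y_u <- lim[["upper"]] / n_bn
  z <- qnorm(1 - (1 - conf) / 2)
  se_fun <- if (is.null(curve$vcov)) function(d) rep(0, length(d)) else
    function(d) yield_se(curve, d)
  upper_band <- function(d) predict_yield(curve, d) + z * se_fun(d)
  lower_band <- function(d) predict_yield(curve, d) - z * se_fun(d)

  dose <- invert_dose(curve, n_mn / n_bn)

  ci_low <- if (upper_band(0) >= y_l) 0 else {
    if (upper_band(d_max) < y_l) {
      abort(sprintf("lower confidence limit exceeds d_max = %g Gy", d_max))
    }
    uniroot(function(d) upper_band(d) - y_l, c(0, d_max), tol = 1e-10)$root
  }
  if (lower_band(d_max) < y_u) {
    abort(sprintf("upper confidence limit exceeds d_max = %g Gy", d_max))
  }
  ci_high <- if (lower_band(0) >= y_u) 0 else
    uniroot(function(d) lower_band(d) - y_u, c(0, d_max), tol = 1e-10)$root
  c(dose = dose, ci_low = ci_low, ci_high = ci_high)
}

#' Estimate absorbed doses for a table of samples
#'
#' For each sample, converts the observed MN count to a yield, inverts the
#' calibration curve for the point dose, and constructs 95% confidence limits
#' that merge the two error sources of cytogenetic dose estimation: Poisson
#' counting error on the observed MN count (exact Garwood chi-square limits
#' by default) and calibration-curve coefficient uncertainty (delta-method
#' band `y(D) +/- 1.96 * se(D)`). The lower dose limit is the smallest dose
#' at which the upper curve band reaches the lower yield limit, and
#' conversely for the upper limit (the standard curve-crossing construction
#' of biological dosimetry). A triage class is attached from the point
#' estimate.
#'
#' @param samples A data frame with columns `sample_id`, `n_bn`, `n_mn` and
#'   optionally `delivered_dose` and `source_label` (carried through).
#' @param curve An [lq_curve()] or [fit_lq()] object (a covariance matrix is
#'   required for the curve-error component; without one the band is the
#'   curve itself).
#' @param cutoff Triage cutoff in Gy.
#' @param conf Confidence level.
#' @param d_max Upper search bound in Gy for the confidence limits; a limit
#'   that would exceed it raises an error naming the bound.
#' @param ci_method `"exact"` for Garwood Poisson limits (default) or
#'   `"approx"` for the normal approximation.
#' @return A tibble with columns `sample_id`, `n_bn`, `n_mn`, `yield`,
#'   `dose_gy`, `ci_low_gy`, `ci_high_gy`, `triage_class` and `extrapolated`
#'   (TRUE when the point estimate exceeds the maximum calibrated dose, with
#'   a warning), plus any carried-through columns.
#' @examples
#' crv <- published_curve("fully-automated")
#' samples <- tibble::tibble(sample_id = "s1", n_bn = 1800, n_mn = 423)
#' estimate_dose(samples, crv)
#' @export
estimate_dose <- function(samples, curve, cutoff = 1.5, conf = 0.95,
                          d_max = 10, ci_method = c("exact", "approx")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(curve, "lq_curve"))
  samples <- tibble::as_tibble(samples)
  needed <- c("sample_id", "n_bn", "n_mn")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("missing sample column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(samples$n_bn <= 0)) abort("n_bn must be positive")

  res <- purrr::map(seq_len(nrow(samples)), function(i) {
    dose_ci_single(curve, samples$n_mn[i], samples$n_bn[i], conf = conf,
                   d_max = d_max, method = ci_method)
  })
  res <- do.call(rbind, res)

  out <- samples
  out$yield <- out$n_mn / out$n_bn
  out$dose_gy <- as.vector(res[, "dose"])
  out$ci_low_gy <- as.vector(res[, "ci_low"])
  out$ci_high_gy <- as.vector(res[, "ci_high"])
  out$triage_class <- classify_triage(out$dose_gy, cutoff)
  d_cal <- curve$d_max_cal
  out$extrapolated <- if (is.null(d_cal)) NA else out$dose_gy > d_cal
  if (isTRUE(any(out$extrapolated))) {
    warn(sprintf("%d estimate(s) exceed the maximum calibrated dose (%g Gy)",
                 sum(out$extrapolated), d_cal))
  }
  out
}
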