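#' Construct a linear-quadratic yield curve
#'
#' Builds a curve object for the model `y = c + alpha * D + beta * D^2`
#' relating the MN yield per BN cell `y` to absorbed dose `D` in Gy, with
#' background frequency `c`. Use this to work with published coefficients;
#' curves estimated from data come from [fit_lq()].
#'
#' @param c Background (spontaneous) MN frequency per BN cell, >= 0.
#' @param alpha Linear coefficient per Gy, >= 0.
#' @param beta Quadratic coefficient per Gy^2, >= 0.
#' @param vcov Optional 3x3 symmetric covariance matrix of `(c, alpha, beta)`;
#'   needed for curve-error confidence bands.
#' @param label Optional free-text label.
#' @return An object of class `lq_curve`.
#' @examples
#' crv <- lq_curve(0.0178, 0.0237, 0.0080)
#' predict_yield(crv, dose = c(0, 2, 4))
#' @export
lq_curve <- function(c, alpha, beta, vcov = NULL, label = NULL) {
  coefs <- c(c = c, alpha = alpha, beta = beta)
  if (any(!is.finite(coefs)) || any(coefs < 0)) {
    abort("coefficients must be finite and non-negative")
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    if (!all(dim(vcov) == c(3, 3)) || max(abs(vcov - t(vcov))) > 1e-12 * (1 + max(abs(vcov)))) {
      abort("vcov must be a symmetric 3x3 matrix")
    }
    dimnames(vcov) <- list(names(coefs), names(coefs))
  }
  structure(
    list(coefficients = coefs, vcov = vcov,
         se = if (is.null(vcov)) rep(NA_real_, 3) else sqrt(diag(vcov)),
         label = label),
    class = "lq_curve"
  )
}

#' Fit a linear-quadratic calibration curve by Poisson maximum likelihood
#'
#' Maximises the aggregated Poisson log-likelihood
#' `L(c, alpha, beta) = sum_i (M_i * log(lambda_i) - N_i * lambda_i)` with
#' `lambda_i = c + alpha * D_i + beta * D_i^2`, where `M_i` is the total MN
#' count and `N_i` the number of scored BN cells at dose `D_i`, subject to
#' `c, alpha, beta >= 0`. The coefficient covariance is the inverse of the
#' observed Fisher information
#' `I_jk = sum_i N_i * x_ij * x_ik / lambda_i`, `x_i = (1, D_i, D_i^2)`,
#' at the optimum.
#'
#' Optimisation is box-constrained quasi-Newton (L-BFGS-B) with analytic
#' gradient, started from unweighted least squares on `(D_i, M_i / N_i)`
#' clipped to be at least 1e-6; this is deterministic and, for this smooth
#' 3-parameter likelihood, converges in a handful of iterations.
#'
#' @param data A distribution table with columns `dose_gy`, `n_bn` and either
#'   MN-class columns `mn0..mnK` or a pre-aggregated `n_mn` column (the
#'   likelihood depends on the per-dose totals only).
#' @param group Optional name of a column to stratify by (e.g. sex); one
#'   curve is fitted per stratum and a named list of fits is returned.
#' @return An object of classes `lq_fit` and `lq_curve` (or a named list of
#'   them when `group` is given) with elements `coefficients`, `vcov`, `se`,
#'   `loglik`, `n_points`, `converged` and `data`.
#' @examples
#' fit <- fit_lq(cbmn_fixture("table1_fully_automated"))
#' tidy(fit)
#' @export
fit_lq <- function(data, group = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(group)) {
    if (!group %in% names(data)) abort(paste0("no such column: ", group))
    parts <- split(data, data[[group]])
    return(purrr::map(parts, function(part) {
      fit_lq(dplyr::select(part, -dplyr::all_of(group)))
    }))
  }
  if (length(mn_class_cols(data)) > 0) {
    data <- validate_mn_distributions(data, require_fit_points = FALSE)
  }
  data <- add_mn_totals(data)
  dose <- data$dose_gy
  n_bn <- data$n_bn
  n_mn <- data$n_mn
  if (dplyr::n_distinct(dose) < 3) {
    abort("linear-quadratic fit needs at least 3 distinct doses")
  }
  if (all(n_mn == 0)) abort("degenerate data: no micronuclei at any dose")

  X <- cbind(1, dose, dose^2)
  nll <- function(p) {
    lambda <- as.vector(X %*% p)
    if (any(lambda <= 0)) return(.Machine$double.xmax / 2)
    -sum(n_mn * log(lambda) - n_bn * lambda)
  }
  ngr <- function(p) {
    lambda <- as.vector(X %*% p)
    lambda <- pmax(lambda, .Machine$double.xmin)
    -as.vector(t(X) %*% (n_mn / lambda - n_bn))
  }
  start <- pmax(coef(lm(I(n_mn / n_bn) ~ dose + I(dose^2))), 1e-6)
  start[!is.finite(start)] <- 1e-6
  opt <- optim(start, nll, ngr, method = "L-BFGS-B",
               lower = rep(1e-12, 3),
               control = list(factr = 1e5, pgtol = 0, maxit = 500))
  if (opt$convergence != 0) {
    # line searches can stall at machine precision; accept a stationary point
    grad <- ngr(opt$par)
    scale <- max(abs(nll(opt$par)), 1)
    if (max(abs(grad)) > 1e-6 * scale) {
      abort(paste0("Poisson ML fit did not converge: ", opt$message))
    }
  }
  coefs <- setNames(opt$par, c("c", "alpha", "beta"))
  lambda <- as.vector(X %*% coefs)
  info <- t(X) %*% (X * (n_bn / lambda))
  vcov <- solve(info)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(names(coefs), names(coefs))

  structure(
    list(coefficients = coefs, vcov = vcov, se = sqrt(diag(vcov)),
         loglik = -opt$value, n_points = nrow(data), converged = TRUE,
         d_max_cal = max(dose), data = data,
         label = attr(data, "group", exact = TRUE)),
    class = c("lq_fit", "lq_curve")
  )
}

#' Predicted MN yield at a dose
#'
#' Evaluates `y(D) = c + alpha * D + beta * D^2`.
#'
#' @param curve An [lq_curve()] or [fit_lq()] object.
#' @param dose Dose(s) in Gy, >= 0.
#' @return Predicted MN per BN cell, vectorised over `dose`.
#' @export
predict_yield <- function(curve, dose) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(dose < 0)) abort("dose must be non-negative")
  p <- curve$coefficients
  p[["c"]] + p[["alpha"]] * dose + p[["beta"]] * dose^2
}

#' Standard error of the predicted yield
#'
#' Delta-method standard error of `y(D)`: `sqrt(x' V x)` with
#' `x = (1, D, D^2)` and `V` the coefficient covariance.
#'
#' @inheritParams predict_yield
#' @return Standard error of the predicted yield, vectorised over `dose`.
#' @export
yield_se <- function(curve, dose) {
  stopifnot(inherits(curve, "lq_curve"))
  if (any(dose < 0)) abort("dose must be non-negative")
  if (is.null(curve$vcov)) abort("curve has no covariance matrix")
  X <- cbind(1, dose, dose^2)
  sqrt(pmax(rowSums((X %*% curve$vcov) * X), 0))
}

#' @export
print.lq_curve <- function(x, ...) {
  cat("Linear-quadratic MN yield curve: y = c + alpha*D + beta*D^2\n")
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  est <- format(signif(x$coefficients, 4))
  se <- if (all(is.na(x$se))) rep("-", 3) else format(signif(x$se, 3))
  cat(sprintf("  %-6s %10s  (se %s)\n", names(x$coefficients), est, se), sep = "")
  if (inherits(x, "lq_fit")) {
    cat(sprintf("  fitted to %d dose points; log-likelihood %.3f\n",
                x$n_points, x$loglik))
  }
  invisible(x)
}

#' @export
tidy.lq_curve <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se)
  )
}

#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_points = x$n_points,
    converged = x$converged
  )
}

#' Serialise a fitted curve to JSON
#'
#' @param curve An [lq_curve()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "lq_curve"))
  obj <- list(
    model = "linear-quadratic",
    c = unname(curve$coefficients[["c"]]),
    alpha = unname(curve$coefficients[["alpha"]]),
    beta = unname(curve$coefficients[["beta"]]),
    se_c = unname(curve$se[1]), se_alpha = unname(curve$se[2]),
    se_beta = unname(curve$se[3]),
    cov = if (is.null(curve$vcov)) NULL else as.vector(t(curve$vcov)),
    loglik = curve$loglik, n_points = curve$n_points
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"), path)
  invisible(path)
}

#' Read a fitted curve from JSON
#'
#' @param path Path to a JSON file written by [write_curve_json()].
#' @return An [lq_curve()] object.
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  vcov <- if (!is.null(obj$cov)) matrix(obj$cov, 3, 3, byrow = TRUE) else NULL
  lq_curve(obj$c, obj$alpha, obj$beta, vcov = vcov)
}
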