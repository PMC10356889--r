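# Printed per-dose summary values for the pooled fully-automated table,
# used as frozen expectations in the descriptive sweeps.
printed_table1_summary <- tibble::tibble(
  dose_gy = c(0, 0.1, 0.25, 0.5, 0.75, 1, 2, 3, 4),
  dispersion_index = c(1.12, 1.04, 1.11, 1.08, 1.03, 1.03, 1.03, 1.03, 1.03),
  mn_frequency = c(0.021, 0.019, 0.023, 0.033, 0.036, 0.048, 0.103, 0.165, 0.235)
)

# Printed triage metrics per group and scoring mode.
printed_table3_metrics <- tibble::tribble(
  ~group,  ~mode,             ~sensitivity, ~specificity, ~accuracy,
  "all",   "fully-automated", 1.00,         0.20,         0.56,
  "all",   "semi-automated",  1.00,         0.90,         0.94,
  "all",   "manual",          1.00,         0.90,         0.94,
  "x_ray", "fully-automated", 1.00,         0.25,         0.67,
  "x_ray", "semi-automated",  1.00,         0.75,         0.89,
  "x_ray", "manual",          1.00,         0.75,         0.89,
  "gamma", "fully-automated", 1.00,         0.33,         0.56,
  "gamma", "semi-automated",  1.00,         1.00,         1.00,
  "gamma", "manual",          1.00,         1.00,         1.00
)

# Extract the MN-class histogram of a one-row distribution tibble.
row_to_counts_test <- function(row) {
  cols <- grep("^mn[0-9]+$", names(row), value = TRUE)
  cols <- cols[order(as.integer(sub("^mn", "", cols)))]
  as.numeric(row[1, cols])
}

# Independent bisection solver for y(D) = target on an increasing curve.
bisect_dose <- function(f, target, lo = 0, hi = 20, tol = 1e-10) {
  if (f(lo) >= target) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Aggregated Poisson log-likelihood, written independently of the package.
oracle_loglik <- function(p, dose, n_bn, n_mn) {
  lambda <- p[1] + p[2] * dose + p[3] * dose^2
  if (any(lambda <= 0)) return(-Inf)
  sum(n_mn * log(lambda) - n_bn * lambda)
}

# Coarse-to-fine grid search of the same log-likelihood over [0, hi]^3:
# a 1e-3 pass followed by a 1e-4 refinement around the coarse optimum.
oracle_grid_fit <- function(dose, n_bn, n_mn, hi = 0.1) {
  best_over <- function(cs, as, bs) {
    best <- c(NA, NA, NA); best_ll <- -Inf
    for (cc in cs) for (aa in as) {
      lambda0 <- cc + aa * dose
      for (bb in bs) {
        lambda <- lambda0 + bb * dose^2
        if (any(lambda <= 0)) next
        ll <- sum(n_mn * log(lambda) - n_bn * lambda)
        if (ll > best_ll) { best_ll <- ll; best <- c(cc, aa, bb) }
      }
    }
    best
  }
  coarse <- best_over(seq(0, hi, by = 1e-3), seq(0, hi, by = 1e-3),
                      seq(0, hi, by = 1e-3))
  win <- function(x) seq(max(x - 2e-3, 0), min(x + 2e-3, hi), by = 1e-4)
  best_over(win(coarse[1]), win(coarse[2]), win(coarse[3]))
}

# Grid-scan oracle for the curve-crossing confidence limits.
oracle_dose_ci <- function(curve, n_mn, n_bn, d_max = 10, step = 1e-4) {
  lims <- c(
    if (n_mn == 0) 0 else qchisq(0.025, 2 * n_mn) / 2,
    qchisq(0.975, 2 * n_mn + 2) / 2
  ) / n_bn
  z <- qnorm(0.975)
  d <- seq(0, d_max, by = step)
  y <- predict_yield(curve, d)
  se <- yield_se(curve, d)
  upper <- y + z * se
  lower <- y - z * se
  lo <- if (upper[1] >= lims[1]) 0 else d[which(upper >= lims[1])[1]]
  hi <- d[which(lower >= lims[2])[1]]
  c(ci_low = lo, ci_high = hi)
}
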