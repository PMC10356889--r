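#' Packaged CBMN reference tables
#'
#' Returns one of the reference tables shipped with the package: the pooled
#' fully-automated micronucleus (MN) distribution by dose from a six-donor
#' gamma-ray calibration experiment, the corresponding automated-scoring error
#' rates, or the triage contingency tables from a 22-sample blind validation
#' exercise.
#'
#' @param name One of `"table1_fully_automated"` (per-dose MN distributions:
#'   `dose_gy`, `n_bn`, `mn0`..`mn4`), `"table2_error_rates"` (per-dose
#'   automated-scoring error percentages: `dose_gy`, `fp_bn_pct`, `fp_mn_pct`,
#'   `fn_mn_pct`), or `"table3_contingency"` (triage cross-tabulations:
#'   `group`, `mode`, `delivered_class`, `n_est_le`, `n_est_gt`).
#'
#' @return A tibble. The distribution fixture carries a `mode` attribute
#'   (`"fully-automated"`) and a `group` attribute (`"pooled"`).
#'
#' @details All error-rate percentages are expressed per total scored
#'   binucleated (BN) cell. In the contingency fixture, `delivered_class` is
#'   the known delivered-dose triage class (cutoff 1.5 Gy) and `n_est_le` /
#'   `n_est_gt` count samples whose estimated dose fell at or below /
#'   above the cutoff; samples irradiated with 0 Gy are already excluded.
#'
#' @examples
#' cbmn_fixture("table1_fully_automated")
#' cbmn_fixture("table2_error_rates")
#' @export
cbmn_fixture <- function(name = c("table1_fully_automated", "table2_error_rates",
                                  "table3_contingency")) {
  name <- match.arg(name)
  switch(name,
    table1_fully_automated = fixture_table1(),
    table2_error_rates = fixture_table2(),
    table3_contingency = fixture_table3()
  )
}

fixture_table1 <- function() {
  out <- tibble::tribble(
    ~dose_gy, ~n_bn,  ~mn0,  ~mn1, ~mn2, ~mn3, ~mn4,
    0,        16020, 15706,  295,   17,    2,    0,
    0.1,      18000, 17676,  314,   10,    0,    0,
    0.25,     18000, 17602,  382,   13,    1,    2,
    0.5,      18000, 17440,  531,   28,    0,    1,
    0.75,     18000, 17371,  610,   17,    2,    0,
    1,        18000, 17167,  802,   29,    2,    0,
    2,        18000, 16256, 1630,  111,    3,    0,
    3,        17572, 14933, 2400,  220,   18,    1,
    4,        18000, 14295, 3215,  455,   34,    1
  )
  attr(out, "mode") <- "fully-automated"
  attr(out, "group") <- "pooled"
  validate_mn_distributions(out)
}

fixture_table2 <- function() {
  tibble::tribble(
    ~dose_gy, ~fp_bn_pct, ~fp_mn_pct, ~fn_mn_pct,
    0,        0.98,       0.67,       1.12,
    0.1,      0.72,       0.73,       1.02,
    0.25,     0.80,       0.72,       1.33,
    0.5,      1.16,       1.02,       1.77,
    0.75,     1.09,       0.76,       1.68,
    1,        1.02,       1.04,       2.04,
    2,        0.87,       1.36,       4.43,
    3,        1.38,       1.50,       7.37,
    4,        2.20,       1.46,      10.78
  )
}

fixture_table3 <- function() {
  grid <- tidyr::expand_grid(
    group = c("all", "x_ray", "gamma"),
    mode = c("fully-automated", "semi-automated", "manual"),
    delivered_class = c("<=1.5", ">1.5")
  )
  # counts of estimated-class calls (n_est_le at or below cutoff, n_est_gt above)
  counts <- tibble::tribble(
    ~group,  ~mode,             ~delivered_class, ~n_est_le, ~n_est_gt,
    "all",   "fully-automated", "<=1.5",          2,         8,
    "all",   "fully-automated", ">1.5",           0,         8,
    "all",   "semi-automated",  "<=1.5",          9,         1,
    "all",   "semi-automated",  ">1.5",           0,         8,
    "all",   "manual",          "<=1.5",          9,         1,
    "all",   "manual",          ">1.5",           0,         8,
    "x_ray", "fully-automated", "<=1.5",          1,         3,
    "x_ray", "fully-automated", ">1.5",           0,         5,
    "x_ray", "semi-automated",  "<=1.5",          3,         1,
    "x_ray", "semi-automated",  ">1.5",           0,         5,
    "x_ray", "manual",          "<=1.5",          3,         1,
    "x_ray", "manual",          ">1.5",           0,         5,
    "gamma", "fully-automated", "<=1.5",          2,         4,
    "gamma", "fully-automated", ">1.5",           0,         3,
    "gamma", "semi-automated",  "<=1.5",          6,         0,
    "gamma", "semi-automated",  ">1.5",           0,         3,
    "gamma", "manual",          "<=1.5",          6,         0,
    "gamma", "manual",          ">1.5",           0,         3
  )
  dplyr::left_join(grid, counts, by = c("group", "mode", "delivered_class"))
}

#' Published linear-quadratic calibration curves
#'
#' Convenience constructors for the three published pooled calibration curves
#' (fully-automated, semi-automated and manual scoring), built from their
#' printed coefficients and standard errors. The covariance matrix is taken as
#' diagonal in the printed standard errors, since coefficient correlations
#' were not published.
#'
#' @param mode Scoring mode of the published curve.
#' @return An [lq_curve()] object.
#' @examples
#' predict_yield(published_curve("fully-automated"), dose = 2)
#' @export
published_curve <- function(mode = c("fully-automated", "semi-automated", "manual")) {
  mode <- match.arg(mode)
  p <- switch(mode,
    "fully-automated" = list(c = 0.0178, alpha = 0.0237, beta = 0.0080,
                             se = c(0.0016, 0.0039, 0.0012)),
    "semi-automated"  = list(c = 0.0096, alpha = 0.0170, beta = 0.0111,
                             se = c(0.0011, 0.0031, 0.0010)),
    "manual"          = list(c = 0.0197, alpha = 0.0259, beta = 0.0135,
                             se = c(0.0018, 0.0045, 0.0014))
  )
  lq_curve(p$c, p$alpha, p$beta, vcov = diag(p$se^2), label = mode)
}
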