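#' MN frequency of a single distribution
#'
#' The mean micronucleus count per binucleated cell, `sum(k * counts[k]) /
#' n`, the yield `y` of the dose-response model.
#'
#' @param counts Integer vector of MN-class counts; `counts[k + 1]` is the
#'   number of BN cells bearing exactly `k` micronuclei.
#' @return MN per BN cell.
#' @export
mn_frequency <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("MN frequency undefined: no scored cells")
  k <- seq_along(counts) - 1
  sum(k * counts) / n
}

#' Dispersion index of a single distribution
#'
#' The variance-to-mean ratio (sigma^2 / y) of the per-cell MN count, the
#' standard check of the Poisson assumption in cytogenetic dosimetry: 1 under
#' Poisson scoring, above 1 for overdispersed counts. The variance uses the
#' n - 1 denominator.
#'
#' @inheritParams mn_frequency
#' @return Variance-to-mean ratio.
#' @export
dispersion_index <- function(counts) {
  n <- sum(counts)
  if (n <= 1) abort("dispersion index undefined: need more than one cell")
  k <- seq_along(counts) - 1
  total <- sum(k * counts)
  if (total == 0) abort("dispersion index undefined: zero mean MN count")
  m <- total / n
  v <- (sum(k^2 * counts) - n * m^2) / (n - 1)
  v / m
}

#' Poisson overdispersion u score of a single distribution
#'
#' The standard-normal-scaled test score for departure of the dispersion
#' index from its Poisson expectation of 1:
#' `u = (DI - 1) * sqrt((n - 1) / (2 * (1 - 1/X)))` with `X` the total MN
#' count. Values outside (-1.96, 1.96) indicate significant under- or
#' overdispersion at the 5% level.
#'
#' @inheritParams mn_frequency
#' @return Standard-normal-scaled score.
#' @export
u_statistic <- function(counts) {
  n <- sum(counts)
  k <- seq_along(counts) - 1
  total <- sum(k * counts)
  if (n <= 1 || total < 2) abort("u statistic undefined: need n > 1 and at least 2 MN")
  di <- dispersion_index(counts)
  (di - 1) * sqrt((n - 1) / (2 * (1 - 1 / total)))
}

#' Per-dose descriptive statistics of MN distributions
#'
#' Computes, for every dose point, the MN frequency (MN per BN cell), the
#' dispersion index (variance-to-mean ratio) and the overdispersion u score.
#' Statistics that are undefined for a row (e.g. dispersion at zero total MN)
#' are returned as `NA` and flagged rather than raising an error, so whole
#' tables can be summarised in one pass.
#'
#' @param data A validated MN distribution table (see
#'   [validate_mn_distributions()]).
#' @return A tibble with columns `dose_gy`, `n_bn`, `n_mn`, `mn_frequency`,
#'   `dispersion_index`, `u_statistic` and `flagged` (TRUE where any
#'   statistic was undefined).
#' @examples
#' mn_descriptives(cbmn_fixture("table1_fully_automated"))
#' @export
mn_descriptives <- function(data) {
  data <- validate_mn_distributions(data, require_fit_points = FALSE)
  mn_cols <- mn_class_cols(data)
  counts <- as.matrix(data[mn_cols])
  per_row <- purrr::map(seq_len(nrow(data)), function(i) {
    cnt <- counts[i, ]
    freq <- tryCatch(mn_frequency(cnt), error = function(e) NA_real_)
    di <- tryCatch(dispersion_index(cnt), error = function(e) NA_real_)
    u <- tryCatch(u_statistic(cnt), error = function(e) NA_real_)
    tibble::tibble(mn_frequency = freq, dispersion_index = di, u_statistic = u)
  })
  out <- dplyr::bind_cols(
    add_mn_totals(data)[c("dose_gy", "n_bn", "n_mn")],
    dplyr::bind_rows(per_row)
  )
  out$flagged <- is.na(out$mn_frequency) | is.na(out$dispersion_index) |
    is.na(out$u_statistic)
  out
}
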