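#' Automated-scoring error rates from inspection counts
#'
#' Converts visual-inspection counts into the three error percentages of
#' automated MN scoring, each expressed per total scored BN cell:
#' false-positive BN rate = `n_fp_bn / n_bn_auto * 100`,
#' false-positive MN rate = `n_fp_mn / n_bn_auto * 100`,
#' false-negative MN rate = `n_fn_mn / n_bn_auto * 100`.
#'
#' @param records A data frame with columns `dose_gy`, `n_bn_auto` (BN cells
#'   selected by the automated scorer), `n_fp_bn` (auto-selected BN cells
#'   rejected on inspection), `n_fp_mn` (automatically counted MN rejected as
#'   false) and `n_fn_mn` (MN missed by the scorer, found on full review).
#' @return The table with `fp_bn_pct`, `fp_mn_pct`, `fn_mn_pct` columns added.
#' @export
error_rates <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("dose_gy", "n_bn_auto", "n_fp_bn", "n_fp_mn", "n_fn_mn")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(records$n_bn_auto <= 0)) abort("n_bn_auto must be positive")
  if (any(records$n_fp_bn < 0 | records$n_fp_bn > records$n_bn_auto)) {
    abort("n_fp_bn must lie in [0, n_bn_auto]")
  }
  dplyr::mutate(records,
    fp_bn_pct = .data$n_fp_bn / .data$n_bn_auto * 100,
    fp_mn_pct = .data$n_fp_mn / .data$n_bn_auto * 100,
    fn_mn_pct = .data$n_fn_mn / .data$n_bn_auto * 100
  )
}

#' Summarise a per-dose scoring-error table
#'
#' Unweighted arithmetic means of the three error-rate columns across dose
#' points, plus their ranges both including and excluding the unirradiated
#' (0 Gy) point — background scoring errors are qualitatively different from
#' radiation-dose-driven ones, so both conventions are reported.
#'
#' @param rates A data frame with columns `dose_gy`, `fp_bn_pct`,
#'   `fp_mn_pct`, `fn_mn_pct` (e.g. from [error_rates()] or the Table 2
#'   fixture).
#' @return A tibble with one row per statistic (`mean`, `min`, `max`,
#'   `min_excl_0gy`, `max_excl_0gy`) and one column per rate.
#' @examples
#' summarize_error_rates(cbmn_fixture("table2_error_rates"))
#' @export
summarize_error_rates <- function(rates) {
  rates <- tibble::as_tibble(rates)
  needed <- c("dose_gy", "fp_bn_pct", "fp_mn_pct", "fn_mn_pct")
  missing_cols <- setdiff(needed, names(rates))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(rates) == 0) abort("empty rate table")
  nz <- dplyr::filter(rates, .data$dose_gy > 0)
  stat <- function(label, f, d) {
    tibble::tibble(
      statistic = label,
      fp_bn_pct = f(d$fp_bn_pct),
      fp_mn_pct = f(d$fp_mn_pct),
      fn_mn_pct = f(d$fn_mn_pct)
    )
  }
  dplyr::bind_rows(
    stat("mean", mean, rates),
    stat("min", min, rates),
    stat("max", max, rates),
    if (nrow(nz) > 0) stat("min_excl_0gy", min, nz),
    if (nrow(nz) > 0) stat("max_excl_0gy", max, nz)
  )
}

# Remove m micronuclei from a histogram, always demoting cells from the
# currently lowest MN-bearing class (deterministic; conserves cell count).
histogram_remove_mn <- function(counts, m) {
  while (m > 0) {
    k <- which(counts[-1] > 0)[1] + 1  # index of lowest class with >=1 MN
    if (is.na(k)) abort("cannot remove more MN than the histogram contains")
    t <- min(counts[k], m)
    counts[k] <- counts[k] - t
    counts[k - 1] <- counts[k - 1] + t
    m <- m - t
  }
  counts
}

# Add m micronuclei, always promoting cells from the currently lowest class.
histogram_add_mn <- function(counts, m) {
  while (m > 0) {
    k <- which(counts > 0)[1]
    if (k == length(counts)) counts <- c(counts, 0)
    t <- min(counts[k], m)
    counts[k] <- counts[k] - t
    counts[k + 1] <- counts[k + 1] + t
    m <- m - t
  }
  counts
}

correct_histogram <- function(counts, n_fp_bn, n_fp_mn, n_fn_mn,
                              mode = c("semi", "manual")) {
  mode <- match.arg(mode)
  if (counts[1] < n_fp_bn) {
    abort("cannot reject more false-positive BN cells than MN-free cells present")
  }
  counts[1] <- counts[1] - n_fp_bn
  counts <- histogram_remove_mn(counts, n_fp_mn)
  if (mode == "manual") counts <- histogram_add_mn(counts, n_fn_mn)
  counts
}

#' Correct automated MN counts with inspection results
#'
#' Applies visual-inspection corrections to automated-scoring distributions.
#' In semi-automated mode, rejected false-positive BN cells are removed
#' (from the 0-MN class) and false-positive MN are subtracted; in manual mode
#' false-negative MN found on full review are additionally restored. The
#' per-class histogram is adjusted deterministically by moving cells between
#' adjacent MN classes (removals demote cells from the lowest MN-bearing
#' class first; additions promote cells from class 0 first), so that total
#' BN after = total BN before - `n_fp_bn` and, in manual mode, total MN
#' after = total MN before - `n_fp_mn` + `n_fn_mn`.
#'
#' @param dist_auto A validated distribution table of automated counts.
#' @param inspection A data frame with columns `dose_gy`, `n_fp_bn`,
#'   `n_fp_mn`, `n_fn_mn`, one row per dose in `dist_auto`.
#' @param mode `"semi"` or `"manual"`.
#' @return The corrected distribution table.
#' @export
correct_scoring <- function(dist_auto, inspection, mode = c("semi", "manual")) {
  mode <- match.arg(mode)
  dist_auto <- validate_mn_distributions(dist_auto, require_fit_points = FALSE)
  inspection <- tibble::as_tibble(inspection)
  needed <- c("dose_gy", "n_fp_bn", "n_fp_mn", "n_fn_mn")
  missing_cols <- setdiff(needed, names(inspection))
  if (length(missing_cols) > 0) {
    abort(paste0("missing inspection column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(dist_auto$dose_gy %in% inspection$dose_gy)) {
    abort("every dose in dist_auto needs an inspection row")
  }
  insp <- inspection[match(dist_auto$dose_gy, inspection$dose_gy), ]
  mn_cols <- mn_class_cols(dist_auto)
  corrected <- purrr::map(seq_len(nrow(dist_auto)), function(i) {
    correct_histogram(as.numeric(dist_auto[i, mn_cols]),
                      insp$n_fp_bn[i], insp$n_fp_mn[i], insp$n_fn_mn[i],
                      mode = mode)
  })
  k_max <- max(lengths(corrected))
  mat <- t(vapply(corrected, function(x) c(x, rep(0, k_max - length(x))),
                  numeric(k_max)))
  out <- dist_auto["dose_gy"]
  out$n_bn <- rowSums(mat)
  out <- dplyr::bind_cols(out, tibble::as_tibble(
    stats::setNames(as.data.frame(mat), paste0("mn", seq_len(k_max) - 1))
  ))
  validate_mn_distributions(out, require_fit_points = FALSE)
}

#' Build a dose-dependent scoring-error model
#'
#' Stores a grid of per-dose error rates; evaluation at arbitrary dose uses
#' piecewise-linear interpolation between grid points and constant
#' extrapolation beyond the ends. Interpolation (rather than a fitted trend)
#' stays faithful to the measured rates, which are sparse and non-monotone
#' at low dose.
#'
#' @param rates A data frame with columns `dose_gy` (strictly increasing),
#'   `fp_bn_pct`, `fp_mn_pct`, `fn_mn_pct`.
#' @return An object of class `scoring_error_model`.
#' @examples
#' m <- build_error_model(cbmn_fixture("table2_error_rates"))
#' predict(m, dose = c(3.5, 6))
#' @export
build_error_model <- function(rates) {
  rates <- tibble::as_tibble(rates)
  needed <- c("dose_gy", "fp_bn_pct", "fp_mn_pct", "fn_mn_pct")
  missing_cols <- setdiff(needed, names(rates))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(rates) < 2) abort("need at least 2 dose points")
  if (is.unsorted(rates$dose_gy, strictly = TRUE)) {
    abort("dose grid must be strictly increasing")
  }
  if (any(rates$fp_bn_pct < 0 | rates$fp_mn_pct < 0 | rates$fn_mn_pct < 0)) {
    abort("error rates must be non-negative")
  }
  structure(list(rates = rates), class = "scoring_error_model")
}

#' @export
print.scoring_error_model <- function(x, ...) {
  cat("Dose-dependent automated-scoring error model\n")
  cat(sprintf("  grid: %d doses from %g to %g Gy (linear interpolation, flat tails)\n",
              nrow(x$rates), min(x$rates$dose_gy), max(x$rates$dose_gy)))
  invisible(x)
}

#' Evaluate a scoring-error model at arbitrary doses
#'
#' @param object A [build_error_model()] object.
#' @param dose Dose(s) in Gy.
#' @param ... Unused.
#' @return A tibble with `dose_gy` and the three interpolated percentage
#'   columns.
#' @export
predict.scoring_error_model <- function(object, dose, ...) {
  r <- object$rates
  interp <- function(y) approx(r$dose_gy, y, xout = dose, rule = 2)$y
  tibble::tibble(
    dose_gy = dose,
    fp_bn_pct = interp(r$fp_bn_pct),
    fp_mn_pct = interp(r$fp_mn_pct),
    fn_mn_pct = interp(r$fn_mn_pct)
  )
}
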