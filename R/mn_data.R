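#' Validate a table of per-dose micronucleus distributions
#'
#' A calibration table has one row per dose point with columns `dose_gy`,
#' `n_bn` (number of scored binucleated cells) and MN-class columns
#' `mn0`, `mn1`, ..., `mnK` where `mnk` counts the BN cells bearing exactly
#' `k` micronuclei. The number of classes `K` is unrestricted; published
#' tables typically stop at 4 but the assay does not.
#'
#' @param data A data frame of dose points.
#' @param require_fit_points If `TRUE`, additionally require at least two
#'   distinct doses (the minimum for any curve work).
#' @return `data`, as a tibble, invisibly validated (errors describe the
#'   offending row).
#' @export
validate_mn_distributions <- function(data, require_fit_points = TRUE) {
  data <- tibble::as_tibble(data)
  needed <- c("dose_gy", "n_bn")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  mn_cols <- mn_class_cols(data)
  if (length(mn_cols) == 0) {
    abort("no MN-class columns found (expected mn0, mn1, ...)")
  }
  if (nrow(data) == 0) abort("empty dataset: no dose points")
  if (any(!is.finite(data$dose_gy)) || any(data$dose_gy < 0)) {
    abort("doses must be finite and >= 0")
  }
  if (is.unsorted(data$dose_gy, strictly = TRUE)) {
    abort("doses must be strictly increasing")
  }
  counts <- as.matrix(data[mn_cols])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("MN-class counts must be non-negative integers")
  }
  sums <- rowSums(counts)
  bad <- which(sums != data$n_bn)
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d (dose %g Gy): MN-class counts sum to %d but n_bn is %d",
      bad[1], data$dose_gy[bad[1]], sums[bad[1]], data$n_bn[bad[1]]
    ))
  }
  if (require_fit_points && dplyr::n_distinct(data$dose_gy) < 2) {
    abort("at least 2 distinct doses are required")
  }
  invisible(data)
}

mn_class_cols <- function(data) {
  cols <- grep("^mn[0-9]+$", names(data), value = TRUE)
  cols[order(as.integer(sub("^mn", "", cols)))]
}

#' Per-dose MN totals
#'
#' Adds the total micronucleus count `n_mn` (`sum k * mnk`) to a distribution
#' table; a no-op on tables that already carry `n_mn` and no class columns.
#'
#' @param data A validated distribution table.
#' @return The table with an `n_mn` column.
#' @export
add_mn_totals <- function(data) {
  data <- tibble::as_tibble(data)
  mn_cols <- mn_class_cols(data)
  if (length(mn_cols) == 0) {
    if (!"n_mn" %in% names(data)) abort("need MN-class columns or an n_mn column")
    return(data)
  }
  k <- as.integer(sub("^mn", "", mn_cols))
  data$n_mn <- as.vector(as.matrix(data[mn_cols]) %*% k)
  data
}

#' Read a per-dose MN distribution CSV
#'
#' Expects a header `dose_gy,n_bn,mn0,mn1,...,mnK` with one row per dose
#' point; trailing all-zero MN classes are preserved.
#'
#' @param path Path to the CSV file.
#' @param mode Optional scoring-mode label attached as an attribute.
#' @param group Optional stratum label attached as an attribute.
#' @return A validated tibble of dose points.
#' @export
read_mn_distributions <- function(path, mode = NULL, group = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  attr(data, "spec") <- NULL
  attr(data, "problems") <- NULL
  if (nrow(data) == 0) abort("empty distribution file")
  out <- validate_mn_distributions(data, require_fit_points = FALSE)
  if (!is.null(mode)) attr(out, "mode") <- mode
  if (!is.null(group)) attr(out, "group") <- group
  out
}

#' Write a per-dose MN distribution CSV
#'
#' @param data A validated distribution table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mn_distributions <- function(data, path) {
  data <- validate_mn_distributions(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Read per-sample MN observations
#'
#' Expects a header `sample_id,n_bn,n_mn` with optional `delivered_dose`
#' (known dose in Gy, used only for evaluation) and `source_label`
#' (radiation-quality tag) columns.
#'
#' @param path Path to the CSV file.
#' @return A tibble of sample observations.
#' @export
read_samples <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("sample_id", "n_bn", "n_mn")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(data$n_bn <= 0)) abort("n_bn must be positive for every sample")
  if (any(data$n_mn < 0)) abort("n_mn must be non-negative")
  attr(data, "spec") <- NULL
  attr(data, "problems") <- NULL
  tibble::as_tibble(data)
}

#' Write dose estimates to CSV
#'
#' Serialises a table of dose estimates (as produced by [estimate_dose()])
#' with the columns `sample_id,n_bn,n_mn,yield,dose_gy,ci_low_gy,ci_high_gy,
#' triage_class`; numeric fields are written at full precision so a read-back
#' reproduces them.
#'
#' @param estimates A non-empty tibble of dose estimates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_estimates <- function(estimates, path) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0) {
    abort("estimates must be a non-empty data frame")
  }
  cols <- c("sample_id", "n_bn", "n_mn", "yield", "dose_gy",
            "ci_low_gy", "ci_high_gy", "triage_class")
  missing_cols <- setdiff(cols, names(estimates))
  if (length(missing_cols) > 0) {
    abort(paste0("missing estimate column(s): ", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(estimates, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Read dose estimates from CSV
#'
#' @param path Path to a CSV written by [write_dose_estimates()].
#' @return A tibble of dose estimates.
#' @export
read_dose_estimates <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  attr(data, "spec") <- NULL
  attr(data, "problems") <- NULL
  tibble::as_tibble(data)
}
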