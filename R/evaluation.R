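#' Triage confusion matrix against delivered doses
#'
#' Cross-tabulates estimated against delivered triage class at a dose cutoff.
#' "Positive" means delivered dose above the cutoff (the clinically urgent
#' class); a delivered dose exactly at the cutoff is the negative ("<=")
#' class. Samples with a delivered dose of exactly 0 Gy are excluded from
#' the comparison (unirradiated controls are not part of the binary triage
#' question) and counted separately.
#'
#' @param estimates A data frame with a dose estimate column and a
#'   `delivered_dose` column (e.g. from [estimate_dose()] on samples with
#'   known doses).
#' @param cutoff Triage cutoff in Gy.
#' @param dose_col Name of the estimated-dose column.
#' @return An object of class `triage_confusion`: counts `tp`, `fn`, `fp`,
#'   `tn`, the `cutoff`, and `n_excluded_zero_dose`.
#' @export
triage_confusion <- function(estimates, cutoff = 1.5, dose_col = "dose_gy") {
  estimates <- tibble::as_tibble(estimates)
  if (!"delivered_dose" %in% names(estimates)) {
    abort("estimates must carry a delivered_dose column")
  }
  if (!dose_col %in% names(estimates)) {
    abort(paste0("no such column: ", dose_col))
  }
  if (any(is.na(estimates$delivered_dose))) {
    abort("every sample needs a delivered dose")
  }
  n_zero <- sum(estimates$delivered_dose == 0)
  ev <- dplyr::filter(estimates, .data$delivered_dose > 0)
  if (nrow(ev) == 0) {
    abort(sprintf("no evaluable samples (%d excluded at 0 Gy)", n_zero))
  }
  truth_pos <- ev$delivered_dose > cutoff
  est_pos <- ev[[dose_col]] > cutoff
  structure(
    list(
      tp = sum(truth_pos & est_pos),
      fn = sum(truth_pos & !est_pos),
      fp = sum(!truth_pos & est_pos),
      tn = sum(!truth_pos & !est_pos),
      cutoff = cutoff,
      n_excluded_zero_dose = n_zero
    ),
    class = "triage_confusion"
  )
}

#' Build a confusion object directly from cell counts
#'
#' @param tp,fn,fp,tn Non-negative cell counts ("positive" = delivered dose
#'   above the cutoff).
#' @param cutoff Triage cutoff in Gy.
#' @param n_excluded_zero_dose Number of true-0 Gy samples excluded.
#' @return A `triage_confusion` object.
#' @export
as_triage_confusion <- function(tp, fn, fp, tn, cutoff = 1.5,
                                n_excluded_zero_dose = 0) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, cutoff = cutoff,
         n_excluded_zero_dose = n_excluded_zero_dose),
    class = "triage_confusion"
  )
}

#' @export
print.triage_confusion <- function(x, ...) {
  cat(sprintf("Triage confusion matrix (cutoff %g Gy; positive = delivered > cutoff)\n",
              x$cutoff))
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d (%d sample(s) at 0 Gy excluded)\n",
              x$tp, x$fn, x$fp, x$tn, x$n_excluded_zero_dose))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a triage confusion matrix
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`,
#' `accuracy = (tp + tn) / total`. A metric whose denominator is zero is
#' returned as `NA` (flagged undefined), not an error.
#'
#' @param conf A [triage_confusion()] object.
#' @return A tibble with columns `metric`, `value` (unrounded) and `display`
#'   (rounded to 2 decimals for presentation).
#' @export
confusion_metrics <- function(conf) {
  stopifnot(inherits(conf, "triage_confusion"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  values <- c(
    sensitivity = ratio(conf$tp, conf$tp + conf$fn),
    specificity = ratio(conf$tn, conf$tn + conf$fp),
    accuracy = ratio(conf$tp + conf$tn, conf$tp + conf$fn + conf$fp + conf$tn)
  )
  tibble::tibble(
    metric = names(values),
    value = unname(values),
    display = round(unname(values), 2)
  )
}

#' Dose-estimation accuracy against delivered doses
#'
#' Two quality measures of a set of dose estimates with known truth:
#' the coverage accuracy (fraction of samples whose 95% confidence interval
#' contains the delivered dose, boundaries inclusive) and the mean absolute
#' difference between estimated and delivered dose in Gy. Unlike the triage
#' comparison, 0 Gy samples are included; a `nonzero_dose` row restricted to
#' irradiated samples is reported alongside.
#'
#' @param estimates A data frame with columns `dose_gy`, `ci_low_gy`,
#'   `ci_high_gy` and `delivered_dose`.
#' @return A tibble with rows `all` and `nonzero_dose` and columns `subset`,
#'   `n`, `coverage_accuracy`, `mean_abs_diff`.
#' @export
dose_accuracy <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  needed <- c("dose_gy", "ci_low_gy", "ci_high_gy", "delivered_dose")
  missing_cols <- setdiff(needed, names(estimates))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(estimates) == 0) abort("empty estimate table")
  one <- function(label, d) {
    if (nrow(d) == 0) return(NULL)
    tibble::tibble(
      subset = label,
      n = nrow(d),
      coverage_accuracy = mean(d$ci_low_gy <= d$delivered_dose &
                               d$delivered_dose <= d$ci_high_gy),
      mean_abs_diff = mean(abs(d$dose_gy - d$delivered_dose))
    )
  }
  dplyr::bind_rows(
    one("all", estimates),
    one("nonzero_dose", dplyr::filter(estimates, .data$delivered_dose > 0))
  )
}
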