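#' Simulate one per-dose MN distribution
#'
#' Draws an MN count for each of `n_bn` binucleated cells from a Poisson
#' distribution with mean `lambda = predict_yield(curve, dose)`, or from a
#' gamma-mixed Poisson when mild overdispersion is wanted: the gamma shape is
#' chosen as `lambda / (di_target - 1)` so that the count variance is
#' `lambda * di_target`, hitting the target dispersion index in expectation.
#'
#' @param curve Generating [lq_curve()].
#' @param dose Dose in Gy.
#' @param n_bn Number of cells to simulate.
#' @param dispersion `"poisson"` or `"overdispersed"`.
#' @param di_target Target dispersion index (> 1) for the overdispersed
#'   variant.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param min_classes Minimum number of MN classes in the returned histogram
#'   (padded with zeros).
#' @return A one-row distribution tibble (`dose_gy`, `n_bn`, `mn0..mnK`).
#' @export
simulate_mn_distribution <- function(curve, dose, n_bn,
                                     dispersion = c("poisson", "overdispersed"),
                                     di_target = 1.1, seed = NULL,
                                     min_classes = 5) {
  dispersion <- match.arg(dispersion)
  if (!is.null(seed)) set.seed(seed)
  if (n_bn < 1) abort("n_bn must be at least 1")
  lambda <- predict_yield(curve, dose)
  x <- draw_mn_counts(n_bn, lambda, dispersion, di_target)
  counts_to_row(x, dose, min_classes)
}

draw_mn_counts <- function(n, lambda, dispersion, di_target) {
  if (lambda == 0) return(integer(n))
  if (dispersion == "poisson") return(rpois(n, lambda))
  if (di_target <= 1) abort("di_target must exceed 1 for overdispersed counts")
  shape <- lambda / (di_target - 1)
  rpois(n, rgamma(n, shape = shape, rate = shape / lambda))
}

counts_to_row <- function(x, dose, min_classes = 5) {
  k_max <- max(max(x), min_classes - 1)
  counts <- tabulate(x + 1, nbins = k_max + 1)
  row <- tibble::as_tibble(stats::setNames(
    as.list(counts), paste0("mn", 0:k_max)
  ))
  dplyr::bind_cols(tibble::tibble(dose_gy = dose, n_bn = length(x)), row)
}

row_to_counts <- function(row) {
  cols <- mn_class_cols(row)
  as.numeric(row[1, cols])
}

pad_mn_classes <- function(rows) {
  all_cols <- unique(unlist(lapply(rows, mn_class_cols)))
  k <- sort(as.integer(sub("^mn", "", all_cols)))
  cols <- paste0("mn", k)
  dplyr::bind_rows(lapply(rows, function(r) {
    for (cl in setdiff(cols, names(r))) r[[cl]] <- 0
    r[c("dose_gy", "n_bn", cols)]
  }))
}

#' Simulate a calibration dataset
#'
#' One simulated distribution per dose on a common MN-class grid.
#'
#' @inheritParams simulate_mn_distribution
#' @param doses Strictly increasing dose grid in Gy.
#' @param n_bn_per_dose Cells per dose point (scalar or one per dose).
#' @return A validated distribution tibble.
#' @export
simulate_calibration <- function(curve, doses, n_bn_per_dose,
                                 dispersion = c("poisson", "overdispersed"),
                                 di_target = 1.1, seed = NULL) {
  dispersion <- match.arg(dispersion)
  if (!is.null(seed)) set.seed(seed)
  n_bn_per_dose <- rep_len(n_bn_per_dose, length(doses))
  rows <- purrr::map(seq_along(doses), function(i) {
    lambda <- predict_yield(curve, doses[i])
    x <- draw_mn_counts(n_bn_per_dose[i], lambda, dispersion, di_target)
    counts_to_row(x, doses[i])
  })
  validate_mn_distributions(pad_mn_classes(rows))
}

#' Corrupt a clean distribution with automated-scoring errors
#'
#' Emulates an automated scorer reading the slide that the clean
#' distribution describes: micronuclei are missed (false negatives, removed
#' from randomly chosen micronuclei), spurious micronuclei are added to
#' randomly chosen cells (false positives), and spurious MN-free BN cells
#' are added (false-positive BN). Error counts are binomial draws against
#' the model's per-BN-cell percentage at each row's dose; false-negative
#' removals are capped at the available MN and the applied (post-cap) counts
#' are recorded. The returned inspection record undoes the corruption
#' exactly: [correct_scoring()] in manual mode restores the original BN and
#' MN totals for any seed.
#'
#' @param dist A validated clean distribution table.
#' @param model A [build_error_model()] object.
#' @param seed Optional integer seed.
#' @param fp_bn_with_mn If `TRUE`, spurious BN cells carry MN at the
#'   false-positive MN rate instead of always being MN-free.
#' @return A list with elements `auto` (corrupted distribution table) and
#'   `inspection` (tibble `dose_gy`, `n_bn_auto`, `n_mn_auto`, `n_fp_bn`,
#'   `n_fp_mn`, `n_fn_mn`, `fn_capped`).
#' @export
corrupt_scoring <- function(dist, model, seed = NULL, fp_bn_with_mn = FALSE) {
  stopifnot(inherits(model, "scoring_error_model"))
  dist <- validate_mn_distributions(dist, require_fit_points = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rates <- predict(model, dist$dose_gy)
  mn_cols <- mn_class_cols(dist)

  out <- purrr::map(seq_len(nrow(dist)), function(i) {
    counts <- as.numeric(dist[i, mn_cols])
    n_bn <- sum(counts)
    per_cell <- rep(seq_along(counts) - 1, counts)  # MN count of each cell

    # miss MN: each truth MN is dropped with the per-cell FN probability
    n_fn_target <- rbinom(1, n_bn, min(rates$fn_mn_pct[i] / 100, 1))
    mn_owner <- rep(seq_along(per_cell), per_cell)
    n_fn <- min(n_fn_target, length(mn_owner))
    if (n_fn > 0) {
      drop <- sample(length(mn_owner), n_fn)
      lost <- tabulate(mn_owner[drop], nbins = length(per_cell))
      per_cell <- per_cell - lost
    }
    # spurious MN on randomly chosen cells
    n_fp <- rbinom(1, n_bn, min(rates$fp_mn_pct[i] / 100, 1))
    if (n_fp > 0) {
      gain <- tabulate(sample(length(per_cell), n_fp, replace = TRUE),
                       nbins = length(per_cell))
      per_cell <- per_cell + gain
    }
    # spurious BN cells
    n_fp_bn <- rbinom(1, n_bn, min(rates$fp_bn_pct[i] / 100, 1))
    if (n_fp_bn > 0) {
      extra <- if (fp_bn_with_mn) {
        rbinom(n_fp_bn, 1, min(rates$fp_mn_pct[i] / 100, 1))
      } else {
        integer(n_fp_bn)
      }
      per_cell <- c(per_cell, extra)
      n_fp <- n_fp + sum(extra)
    }
    list(
      row = counts_to_row(per_cell, dist$dose_gy[i]),
      insp = tibble::tibble(
        dose_gy = dist$dose_gy[i],
        n_bn_auto = length(per_cell),
        n_mn_auto = sum(per_cell),
        n_fp_bn = n_fp_bn,
        n_fp_mn = n_fp,
        n_fn_mn = n_fn,
        fn_capped = n_fn < n_fn_target
      )
    )
  })
  list(
    auto = validate_mn_distributions(pad_mn_classes(purrr::map(out, "row")),
                                     require_fit_points = FALSE),
    inspection = dplyr::bind_rows(purrr::map(out, "insp"))
  )
}

#' Simulate a complete CBMN study
#'
#' Generates a full seeded experiment: a clean calibration dataset from a
#' generating curve, optionally its automated-scoring corruption with the
#' matching inspection records, and a set of coded ("blind") validation
#' samples with a delivered-dose truth key.
#'
#' @param curve Generating [lq_curve()].
#' @param doses Calibration dose grid in Gy.
#' @param n_bn_per_dose Cells per calibration dose point.
#' @param blind_doses Delivered doses of the blind samples (one sample per
#'   entry; repeat a dose for replicate samples).
#' @param n_bn_blind Cells scored per blind sample.
#' @param error_model Optional [build_error_model()]; when given, corrupted
#'   calibration data and inspection records are included.
#' @param dispersion,di_target Count model, as in
#'   [simulate_mn_distribution()].
#' @param seed Integer seed; the full experiment is a deterministic function
#'   of the configuration and this seed.
#' @return A list with elements `calibration` (clean), `calibration_auto`
#'   and `inspection` (when an error model is given, else `NULL`), `samples`
#'   (tibble `sample_id`, `n_bn`, `n_mn`), `truth` (tibble `sample_id`,
#'   `delivered_dose`) and `config` (the resolved configuration).
#' @examples
#' study <- simulate_study(published_curve("manual"), doses = c(0, 0.5, 1, 2, 4),
#'                         n_bn_per_dose = 2000, blind_doses = c(0.5, 2),
#'                         n_bn_blind = 1000, seed = 1)
#' fit_lq(study$calibration)
#' @export
simulate_study <- function(curve, doses, n_bn_per_dose, blind_doses = numeric(),
                           n_bn_blind = 2000, error_model = NULL,
                           dispersion = c("poisson", "overdispersed"),
                           di_target = 1.1, seed = 1) {
  dispersion <- match.arg(dispersion)
  set.seed(seed)
  calib <- simulate_calibration(curve, doses, n_bn_per_dose,
                                dispersion = dispersion, di_target = di_target)
  corrupted <- if (!is.null(error_model)) {
    corrupt_scoring(calib, error_model)
  }
  samples <- NULL
  truth <- NULL
  if (length(blind_doses) > 0) {
    ids <- sprintf("S%02d", seq_along(blind_doses))
    n_mn <- vapply(blind_doses, function(d) {
      sum(draw_mn_counts(n_bn_blind, predict_yield(curve, d),
                         dispersion, di_target))
    }, numeric(1))
    samples <- tibble::tibble(sample_id = ids, n_bn = n_bn_blind, n_mn = n_mn)
    truth <- tibble::tibble(sample_id = ids, delivered_dose = blind_doses)
  }
  list(
    calibration = calib,
    calibration_auto = if (!is.null(corrupted)) corrupted$auto,
    inspection = if (!is.null(corrupted)) corrupted$inspection,
    samples = samples,
    truth = truth,
    config = list(coefficients = curve$coefficients, doses = doses,
                  n_bn_per_dose = n_bn_per_dose, blind_doses = blind_doses,
                  n_bn_blind = n_bn_blind, dispersion = dispersion,
                  di_target = di_target, seed = seed,
                  error_model = !is.null(error_model))
  )
}
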