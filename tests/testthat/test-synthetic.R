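test_that("simulation is a deterministic function of the seed", {
  crv <- published_curve("manual")
  a <- simulate_calibration(crv, c(0, 1, 2, 4), 2000, seed = 123)
  b <- simulate_calibration(crv, c(0, 1, 2, 4), 2000, seed = 123)
  expect_identical(a, b)
  c <- simulate_calibration(crv, c(0, 1, 2, 4), 2000, seed = 124)
  expect_false(identical(a, c))

  model <- build_error_model(cbmn_fixture("table2_error_rates"))
  s1 <- simulate_study(crv, doses = c(0, 1, 2, 4), n_bn_per_dose = 1000,
                       blind_doses = c(0.5, 2), n_bn_blind = 500,
                       error_model = model, seed = 9)
  s2 <- simulate_study(crv, doses = c(0, 1, 2, 4), n_bn_per_dose = 1000,
                       blind_doses = c(0.5, 2), n_bn_blind = 500,
                       error_model = model, seed = 9)
  expect_identical(s1, s2)
})

test_that("a flat zero curve yields only MN-free cells", {
  flat <- lq_curve(0, 0, 0)
  dist <- simulate_mn_distribution(flat, dose = 3, n_bn = 500, seed = 1)
  expect_equal(dist$mn0, 500)
  expect_equal(add_mn_totals(dist)$n_mn, 0)
})

test_that("simulated yields are unbiased for the generating curve", {
  crv <- published_curve("manual")
  lambda <- 0.0197 + 4 * 0.0259 + 16 * 0.0135
  set.seed(20)
  freqs <- replicate(50, {
    d <- simulate_mn_distribution(crv, dose = 4, n_bn = 18000)
    add_mn_totals(d)$n_mn / d$n_bn
  })
  se_mean <- sqrt(lambda / 18000) / sqrt(50)
  expect_lt(abs(mean(freqs) - lambda), 3 * se_mean)
})

test_that("Poisson draws have unit dispersion index on average", {
  crv <- published_curve("manual")
  set.seed(7)
  dis <- replicate(200, {
    d <- simulate_mn_distribution(crv, dose = 1, n_bn = 2000)
    dispersion_index(row_to_counts_test(d))
  })
  expect_gte(mean(dis), 0.98)
  expect_lte(mean(dis), 1.02)
})

test_that("the overdispersed variant raises the dispersion index toward target", {
  crv <- published_curve("manual")
  set.seed(8)
  dis <- replicate(100, {
    d <- simulate_mn_distribution(crv, dose = 2, n_bn = 4000,
                                  dispersion = "overdispersed", di_target = 1.12)
    dispersion_index(row_to_counts_test(d))
  })
  expect_gt(mean(dis), 1.05)
  expect_lt(mean(dis), 1.2)
})

test_that("an all-zero error model corrupts nothing", {
  crv <- published_curve("manual")
  clean <- simulate_calibration(crv, c(0, 2, 4), 1000, seed = 5)
  none <- build_error_model(tibble::tibble(
    dose_gy = c(0, 4), fp_bn_pct = 0, fp_mn_pct = 0, fn_mn_pct = 0
  ))
  out <- corrupt_scoring(clean, none, seed = 5)
  expect_equal(as.data.frame(out$auto), as.data.frame(clean))
  expect_true(all(out$inspection$n_fp_bn == 0))
  expect_true(all(out$inspection$n_fp_mn == 0))
  expect_true(all(out$inspection$n_fn_mn == 0))
})

test_that("corruption followed by manual correction restores totals exactly", {
  crv <- published_curve("manual")
  model <- build_error_model(cbmn_fixture("table2_error_rates"))
  for (seed in c(1, 2, 3, 4, 5)) {
    clean <- simulate_calibration(crv, c(0, 0.5, 2, 4), 3000, seed = seed)
    out <- corrupt_scoring(clean, model, seed = seed + 100)
    restored <- add_mn_totals(
      correct_scoring(out$auto, out$inspection, "manual")
    )
    truth <- add_mn_totals(clean)
    expect_equal(restored$n_bn, truth$n_bn)
    expect_equal(restored$n_mn, truth$n_mn)
    # inspection records are consistent with the corrupted table
    auto_tot <- add_mn_totals(out$auto)
    expect_equal(out$inspection$n_bn_auto, auto_tot$n_bn)
    expect_equal(out$inspection$n_mn_auto, auto_tot$n_mn)
  }
})

test_that("corruption draws match the binomial means of the error model", {
  crv <- published_curve("manual")
  model <- build_error_model(cbmn_fixture("table2_error_rates"))
  n_bn <- 18000
  clean <- simulate_calibration(crv, c(0, 4), n_bn, seed = 42)
  clean4 <- clean[clean$dose_gy == 4, ]
  set.seed(99)
  draws <- purrr::map(1:100, function(i) corrupt_scoring(clean4, model)$inspection)
  fp <- vapply(draws, function(d) d$n_fp_mn, numeric(1))
  fn <- vapply(draws, function(d) d$n_fn_mn, numeric(1))
  exp_fp <- n_bn * 0.0146
  exp_fn <- n_bn * 0.1078
  sd_fp <- sqrt(n_bn * 0.0146 * (1 - 0.0146)) / sqrt(100)
  sd_fn <- sqrt(n_bn * 0.1078 * (1 - 0.1078)) / sqrt(100)
  expect_lt(abs(mean(fp) - exp_fp), 3 * sd_fp)
  expect_lt(abs(mean(fn) - exp_fn), 3 * sd_fn)
})

test_that("a simulated study supports the full pipeline", {
  crv <- published_curve("manual")
  model <- build_error_model(cbmn_fixture("table2_error_rates"))
  study <- simulate_study(crv, doses = c(0, 0.25, 0.5, 1, 2, 3, 4),
                          n_bn_per_dose = 6000,
                          blind_doses = c(0, 0.5, 1, 2, 3),
                          n_bn_blind = 2000, error_model = model, seed = 31)
  fit <- fit_lq(study$calibration)
  # generating coefficients inside 3 fitted SEs (single-seed smoke check)
  expect_true(all(abs(fit$coefficients - crv$coefficients) < 3 * fit$se))

  est <- estimate_dose(study$samples, fit)
  est <- dplyr::left_join(est, study$truth, by = "sample_id")
  expect_true(all(est$ci_low_gy <= est$dose_gy & est$dose_gy <= est$ci_high_gy))
  rep <- dose_accuracy(est)
  expect_gte(rep$coverage_accuracy[rep$subset == "all"], 0.6)
  conf <- triage_confusion(est)
  expect_equal(conf$n_excluded_zero_dose, 1)
  expect_equal(conf$tp + conf$fn + conf$fp + conf$tn, 4)
})
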