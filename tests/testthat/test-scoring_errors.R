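test_that("error rates evaluate the per-BN-cell percentage definitions", {
  rec <- tibble::tibble(dose_gy = 4, n_bn_auto = 18000,
                        n_fp_bn = 396, n_fp_mn = 263, n_fn_mn = 1940)
  rates <- error_rates(rec)
  expect_equal(round(rates$fp_bn_pct, 2), 2.20)
  expect_equal(round(rates$fp_mn_pct, 2), 1.46)
  expect_equal(round(rates$fn_mn_pct, 2), 10.78)

  zero <- error_rates(tibble::tibble(dose_gy = 0, n_bn_auto = 1000,
                                     n_fp_bn = 0, n_fp_mn = 0, n_fn_mn = 0))
  expect_equal(c(zero$fp_bn_pct, zero$fp_mn_pct, zero$fn_mn_pct), c(0, 0, 0))

  all_fp <- error_rates(tibble::tibble(dose_gy = 0, n_bn_auto = 50,
                                       n_fp_bn = 50, n_fp_mn = 0, n_fn_mn = 0))
  expect_equal(all_fp$fp_bn_pct, 100)

  expect_error(error_rates(tibble::tibble(dose_gy = 0, n_bn_auto = 0,
                                          n_fp_bn = 0, n_fp_mn = 0, n_fn_mn = 0)),
               "positive")
})

test_that("rate reconstruction from integer counts is the identity", {
  t2 <- cbmn_fixture("table2_error_rates")
  n <- 10000  # divisible by the two-decimal rate denominators
  recon <- tibble::tibble(
    dose_gy = t2$dose_gy, n_bn_auto = n,
    n_fp_bn = round(t2$fp_bn_pct / 100 * n),
    n_fp_mn = round(t2$fp_mn_pct / 100 * n),
    n_fn_mn = round(t2$fn_mn_pct / 100 * n)
  )
  rates <- error_rates(recon)
  expect_equal(rates$fp_bn_pct, t2$fp_bn_pct)
  expect_equal(rates$fp_mn_pct, t2$fp_mn_pct)
  expect_equal(rates$fn_mn_pct, t2$fn_mn_pct)
})

test_that("the error-table summary reproduces the published means and ranges", {
  summ <- summarize_error_rates(cbmn_fixture("table2_error_rates"))
  means <- summ[summ$statistic == "mean", ]
  expect_equal(round(means$fp_bn_pct, 2), 1.14)
  expect_equal(round(means$fp_mn_pct, 2), 1.03)
  expect_equal(round(means$fn_mn_pct, 2), 3.50)
  expect_equal(summ$fn_mn_pct[summ$statistic == "min"], 1.02)
  expect_equal(summ$fn_mn_pct[summ$statistic == "max"], 10.78)
  # FP MN range depends on whether the unirradiated row is included
  expect_equal(summ$fp_mn_pct[summ$statistic == "min"], 0.67)
  expect_equal(summ$fp_mn_pct[summ$statistic == "min_excl_0gy"], 0.72)

  single <- summarize_error_rates(
    tibble::tibble(dose_gy = 1, fp_bn_pct = 1, fp_mn_pct = 2, fn_mn_pct = 3)
  )
  expect_equal(unlist(single[single$statistic == "mean", -1], use.names = FALSE),
               c(1, 2, 3))
})

test_that("count correction applies the deterministic bookkeeping rule", {
  dist <- tibble::tibble(dose_gy = 1, n_bn = 100, mn0 = 98, mn1 = 2)
  insp <- tibble::tibble(dose_gy = 1, n_fp_bn = 1, n_fp_mn = 1, n_fn_mn = 0)
  semi <- correct_scoring(dist, insp, "semi")
  expect_equal(semi$n_bn, 99)
  expect_equal(add_mn_totals(semi)$n_mn, 1)
  expect_equal(c(semi$mn0, semi$mn1), c(98, 1))

  # zero-error records are the identity in both modes
  none <- tibble::tibble(dose_gy = 1, n_fp_bn = 0, n_fp_mn = 0, n_fn_mn = 0)
  expect_equal(as.data.frame(correct_scoring(dist, none, "semi")),
               as.data.frame(dist))
  expect_equal(as.data.frame(correct_scoring(dist, none, "manual")),
               as.data.frame(dist))
})

test_that("correction conserves totals per its defining identities", {
  set.seed(11)
  for (i in 1:20) {
    counts <- c(rpois(1, 500) + 50, rpois(1, 60) + 10, rpois(1, 10), rpois(1, 3))
    n_bn <- sum(counts)
    n_mn <- sum((0:3) * counts)
    dist <- tibble::tibble(dose_gy = 1, n_bn = n_bn, mn0 = counts[1],
                           mn1 = counts[2], mn2 = counts[3], mn3 = counts[4])
    insp <- tibble::tibble(
      dose_gy = 1,
      n_fp_bn = sample(0:5, 1),
      n_fp_mn = sample(0:min(5, n_mn), 1),
      n_fn_mn = sample(0:8, 1)
    )
    man <- add_mn_totals(correct_scoring(dist, insp, "manual"))
    expect_equal(man$n_bn, n_bn - insp$n_fp_bn)
    expect_equal(man$n_mn, n_mn - insp$n_fp_mn + insp$n_fn_mn)
    sem <- add_mn_totals(correct_scoring(dist, insp, "semi"))
    expect_equal(sem$n_bn, n_bn - insp$n_fp_bn)
    expect_equal(sem$n_mn, n_mn - insp$n_fp_mn)
  }
})

test_that("impossible corrections raise inconsistency errors", {
  dist <- tibble::tibble(dose_gy = 1, n_bn = 3, mn0 = 1, mn1 = 2)
  insp <- tibble::tibble(dose_gy = 1, n_fp_bn = 2, n_fp_mn = 0, n_fn_mn = 0)
  expect_error(correct_scoring(dist, insp, "semi"), "MN-free")
  insp2 <- tibble::tibble(dose_gy = 1, n_fp_bn = 0, n_fp_mn = 5, n_fn_mn = 0)
  expect_error(correct_scoring(dist, insp2, "semi"), "more MN")
})

test_that("the interpolated error model reproduces and interpolates the grid", {
  model <- build_error_model(cbmn_fixture("table2_error_rates"))
  at4 <- predict(model, 4)
  expect_equal(c(at4$fp_bn_pct, at4$fp_mn_pct, at4$fn_mn_pct),
               c(2.20, 1.46, 10.78))
  expect_equal(predict(model, 3.5)$fn_mn_pct, (7.37 + 10.78) / 2)
  # constant extrapolation beyond the grid
  expect_equal(as.data.frame(predict(model, 6)[-1]),
               as.data.frame(predict(model, 4)[-1]))
  expect_equal(as.data.frame(predict(model, -1)[-1]),
               as.data.frame(predict(model, 0)[-1]))

  bad <- cbmn_fixture("table2_error_rates")[c(2, 1, 3), ]
  expect_error(build_error_model(bad), "increasing")
  expect_error(build_error_model(cbmn_fixture("table2_error_rates")[1, ]),
               "at least 2")
})
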