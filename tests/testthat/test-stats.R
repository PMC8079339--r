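test_that("normality screen is calibrated on normal and exponential samples", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rnorm(200))$p_value
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rexp(200))$p_value
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.9)
})

test_that("normality screen flags degenerate and undersized groups", {
  res <- normality_screen(rep(3.2, 20))
  expect_identical(res$flag, "degenerate_constant")
  expect_true(is.na(res$p_value))
  expect_identical(normality_screen(c(1, 2, 3))$flag, "too_few")

  grouped <- normality_screen(
    tibble::tibble(value = c(rnorm(30), rep(1, 30)),
                   g = rep(c("a", "b"), each = 30)),
    value = "value", group = "g")
  expect_equal(nrow(grouped), 2L)
  expect_identical(grouped$flag[grouped$groups == "b"], "degenerate_constant")
})

test_that("Kruskal-Wallis agrees with the rank-sum formula on tiny groups", {
  configs <- list(
    list(v = c(1, 2, 4, 3, 5, 6), g = rep(c("a", "b"), each = 3)),
    list(v = c(10, 3, 7, 2, 9, 1, 8, 5), g = rep(c("a", "b"), each = 4)),
    list(v = c(1, 4, 7, 2, 5, 8, 3, 6, 9), g = rep(c("a", "b", "c"), each = 3))
  )
  for (cf in configs) {
    got <- compare_methods(tibble::tibble(value = cf$v, method = cf$g),
                           value = "value")
    expect_equal(got$statistic, brute_kruskal_h(cf$v, cf$g), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis comparison is calibrated and handles total ties", {
  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    d <- tibble::tibble(value = rnorm(20), method = rep(c("a", "b"), each = 10))
    compare_methods(d, "value")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)

  pow <- vapply(1:200, function(s) {
    set.seed(s)
    d <- tibble::tibble(value = c(rnorm(20), rnorm(20, 2)),
                        method = rep(c("a", "b"), each = 20))
    compare_methods(d, "value")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.95)

  tied <- compare_methods(
    tibble::tibble(value = rep(0.5, 12), method = rep(c("a", "b"), 6)), "value")
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_identical(tied$flag, "all_tied")
})

test_that("point-biserial factor correlations obey the textbook invariances", {
  tb <- factor_table(simulate_metric_cohort(40, seed = 1))
  fc <- factor_correlation(tb)

  # affine rescaling of DSC leaves r unchanged
  tb2 <- tb
  tb2$dsc <- 3 * tb$dsc - 1
  fc2 <- factor_correlation(tb2)
  expect_equal(fc$r, fc2$r, tolerance = 1e-12)

  # flipped indicator flips the sign: apex vs non-apex
  r_apex <- fc$r[fc$factor == "localisation" & fc$stratum == "apex"]
  r_flip <- iplconcord:::point_biserial(tb$region != "apex", tb$dsc)$r
  expect_equal(r_flip, -r_apex, tolerance = 1e-12)

  # same DSC values inside and outside a stratum give r = 0
  y <- rep(c(1, 2, 3), 2)
  expect_equal(iplconcord:::point_biserial(rep(c(TRUE, FALSE), each = 3), y)$r, 0)

  # perfect separation gives |r| = 1
  sep <- iplconcord:::point_biserial(rep(c(TRUE, FALSE), each = 4),
                                     rep(c(1, 0), each = 4))
  expect_equal(abs(sep$r), 1, tolerance = 1e-12)

  # single-class indicator is reported missing, not an error
  mono <- iplconcord:::point_biserial(rep(TRUE, 10), rnorm(10))
  expect_true(is.na(mono$r))
  expect_identical(mono$flag, "single_class")
})

test_that("factor table strata partition the lesions", {
  tb <- factor_table(simulate_metric_cohort(60, seed = 2))
  expect_true(all(tb$region %in% c("apex", "mid", "base")))
  expect_false(anyNA(tb$psa_bin))
  expect_false(anyNA(tb$suvmax_bin))
  # volume indicators are nested: >=20% implies >=15% implies >=10% ...
  expect_true(all(tb$vol_ge_20 <= tb$vol_ge_15))
  expect_true(all(tb$vol_ge_15 <= tb$vol_ge_10))
  expect_true(all(tb$vol_ge_10 <= tb$vol_ge_5))
})
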