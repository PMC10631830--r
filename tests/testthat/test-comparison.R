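test_that("regression agreement matches closed-form least squares", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(linear_regression_r2(x, 2 * x + 1))
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)

  expect_error(linear_regression_r2(rep(3, 5), x),
               class = "pvloopr_degenerate_regressor")

  set.seed(10)
  xs <- rnorm(10, 50, 10)
  ys <- 0.8 * xs + rnorm(10, 0, 5)
  expect_equal(linear_regression_r2(xs, ys)$r2, pearson_r2_oracle(xs, ys),
               tolerance = 1e-12)
})

test_that("percent Bland-Altman matches the elementwise oracle", {
  b <- c(10, 12, 14, 16)
  same <- bland_altman_percent(b, b)
  expect_equal(same$bias_pct, 0)
  expect_equal(same$loa_low_pct, 0)
  expect_equal(same$loa_high_pct, 0)

  prop <- bland_altman_percent(1.1 * b, b)
  expect_equal(prop$bias_pct, 100 * 0.1 / 1.05, tolerance = 1e-12) # 9.52%
  expect_equal(prop$sd_pct, 0, tolerance = 1e-12)

  set.seed(21)
  a <- runif(8, 50, 150)
  bb <- a * runif(8, 0.8, 1.2)
  got <- bland_altman_percent(a, bb)
  want <- ba_oracle(a, bb)
  expect_equal(got$bias_pct, unname(want["bias"]), tolerance = 1e-12)
  expect_equal(got$loa_low_pct, unname(want["lo"]), tolerance = 1e-12)
  expect_equal(got$loa_high_pct, unname(want["hi"]), tolerance = 1e-12)

  expect_error(bland_altman_percent(c(1, -2), c(1, 2)),
               class = "pvloopr_domain")
  # antisymmetry of the bias under argument exchange
  expect_equal(bland_altman_percent(a, bb)$bias_pct,
               -bland_altman_percent(bb, a)$bias_pct, tolerance = 1e-12)
})

test_that("paired t-test matches the difference-formula oracle", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # textbook-style 5-pair dataset
  a <- c(12.1, 14.3, 9.8, 11.2, 13.4)
  b <- c(11.0, 13.9, 10.4, 10.1, 12.8)
  got <- paired_t_test(a, b)
  want <- t_oracle(a, b)
  expect_equal(got$t, unname(want["t"]), tolerance = 1e-10)
  expect_equal(got$p, unname(want["p"]), tolerance = 1e-10)

  # a fixed shift is detected ever more strongly as n grows
  ps <- vapply(c(4, 8, 16), function(n) {
    set.seed(n)
    base <- rnorm(n, 100, 5)
    paired_t_test(base + 3 + rnorm(n, 0, 0.5), base)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # the exact constant-shift limit
  expect_equal(paired_t_test(c(1, 2, 3) + 2, c(1, 2, 3))$p, 0)

  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("ICC(2,1) matches the two-way ANOVA oracle", {
  a <- c(9, 10, 12, 14, 15, 17)
  expect_equal(icc_absolute_agreement(a, a), 1)

  b <- c(10, 9, 13, 13, 16, 16)
  expect_equal(icc_absolute_agreement(a, b), icc_aov_oracle(a, b),
               tolerance = 1e-10)

  set.seed(99)
  x <- rnorm(200)
  y <- rnorm(200)
  expect_lt(abs(icc_absolute_agreement(x, y)), 0.2)

  expect_error(icc_absolute_agreement(rep(5, 4), rep(5, 4)),
               class = "pvloopr_undefined_icc")
})

test_that("ICC and r2 are invariant to common positive rescaling", {
  set.seed(33)
  a <- runif(10, 40, 120)
  b <- a + rnorm(10, 0, 8)
  expect_equal(icc_absolute_agreement(3 * a, 3 * b),
               icc_absolute_agreement(a, b), tolerance = 1e-12)
  expect_equal(linear_regression_r2(3 * a, 3 * b)$r2,
               linear_regression_r2(a, b)$r2, tolerance = 1e-12)
})

test_that("EDP sensitivity sweep reproduces the default pipeline at 7.5 mmHg", {
  vol <- make_volume_curve(edv = 324, ef = 32, hr = 72, t_es_frac = 0.40)
  bp <- brachial_bp(122, 65)
  sweep <- edp_sensitivity_sweep(vol, bp)
  expect_equal(nrow(sweep), 6)
  expect_equal(sweep$edp, c(3, 7.5, 10, 16, 25, 40))

  base <- compute_all_metrics(compute_noninvasive_loop(vol, bp, edp = 7.5))
  row <- sweep[sweep$edp == 7.5, ]
  for (k in c("sw", "pe", "pva", "espvr", "ea", "ve", "mep_w", "epev")) {
    expect_identical(row[[k]], base[[k]])
  }
  # the sweep genuinely exercises the model
  expect_false(sweep$sw[sweep$edp == 3] == sweep$sw[sweep$edp == 40])
  # VE varies smoothly: adjacent steps stay below the full range
  dve <- abs(diff(sweep$ve))
  expect_lt(max(dve), diff(range(sweep$ve)))

  expect_error(edp_sensitivity_sweep(vol, bp, edp_grid = c(7.5, 150)),
               class = "pvloopr_pressure_ordering")
})

test_that("method comparison composes the four statistics", {
  m <- tibble::tibble(sw = c(5000, 7000, 9000, 11000),
                      ve = c(0.4, 0.5, 0.6, 0.7))
  pairs <- pair_metrics(m, m)
  same <- suppressWarnings(compare_methods(pairs, "sw"))
  expect_equal(same$r2, 1)
  expect_equal(same$bias_pct, 0)
  expect_equal(same$icc, 1)

  m2 <- dplyr::mutate(m, sw = 1.05 * sw)
  prop <- suppressWarnings(compare_methods(pair_metrics(m2, m), "sw"))
  expect_equal(prop$bias_pct, 100 * 0.05 / 1.025, tolerance = 1e-10) # 4.88%
  expect_equal(prop$r2, 1, tolerance = 1e-12)

  expect_error(compare_methods(pairs, "nonexistent"), "not found")
})

test_that("tidy and glance expose agreement results as tibbles", {
  m <- tibble::tibble(sw = c(5000, 7000, 9000, 11000))
  res <- suppressWarnings(
    compare_methods(pair_metrics(m, dplyr::mutate(m, sw = sw * 1.02)), "sw")
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("statistic", "value") %in% names(td)))
  expect_s3_class(glance(res), "tbl_df")
})
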