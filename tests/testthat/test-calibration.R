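test_that("calibration fit matches the closed-form OLS oracle", {
  pts <- data.frame(concentration = c(0, 1, 2), characteristic_value = c(0, 1, 2))
  fit <- fit_calibration(pts)
  expect_equal(fit$slope, 1); expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  pts2 <- linearity_points()
  fit6 <- fit_calibration(pts2)
  oracle6 <- ols_oracle(pts2$concentration, pts2$characteristic_value)
  expect_equal(fit6$slope, oracle6$slope, tolerance = 1e-12)
  expect_equal(fit6$r_squared, oracle6$r_squared, tolerance = 1e-12)
  expect_equal(round(fit6$r_squared, 4), 0.9976)
  # dropping the blank row shifts the 4th decimal
  fit5 <- fit_calibration(pts2[pts2$concentration > 0, ])
  expect_equal(fit5$r_squared, 0.99749, tolerance = 1e-4)
  # order invariance
  fit_rev <- fit_calibration(pts2[rev(seq_len(nrow(pts2))), ])
  expect_equal(fit_rev$r_squared, fit6$r_squared, tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(concentration = c(1, 1),
                                          characteristic_value = c(1, 2))),
               class = "stripwave_config_error")
})

test_that("inverse prediction inverts the fit and clips below range", {
  m <- structure(list(transform = "linear", slope = 2, intercept = 0,
                      r_squared = 1, n_points = 5),
                 class = "calibration_model")
  expect_equal(as.numeric(predict_concentration(m, 1)), 0.5)
  pts <- data.frame(concentration = c(1, 2, 4), characteristic_value = c(3, 5, 9))
  fit <- fit_calibration(pts)
  expect_equal(as.numeric(predict_concentration(fit, 5)), 2, tolerance = 1e-10)
  # instrument linearity table: inverting the 100 ng/ml reading
  fit_ref <- fit_calibration(linearity_points())
  back <- as.numeric(predict_concentration(fit_ref, 0.661529362))
  expect_lt(abs(back - 100) / 100, 0.15)
  neg <- predict_concentration(fit_ref, 0)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "below_range"))
  m0 <- m; m0$slope <- 0
  expect_error(predict_concentration(m0, 1), class = "stripwave_config_error")
})

test_that("replicate statistics reproduce the instrument repeatability rows", {
  # printed statistics were computed from unrounded readouts, so the
  # printed replicate values reproduce them to ~8 significant figures
  st <- replicate_stats(c(0.661529362, 0.720379174, 0.7140643))
  expect_equal(st$mean, 0.698657612, tolerance = 1e-9)
  expect_equal(st$sd, 0.032308661, tolerance = 1e-6)
  expect_equal(st$cv, 0.046243913, tolerance = 1e-6)
  expect_equal(replicate_stats(c(0.012502122, 0.016462386, 0.019128155))$cv,
               0.207975068, tolerance = 1e-6)
  expect_equal(replicate_stats(c(5, 5, 5))$sd, 0)
  expect_error(replicate_stats(5), class = "stripwave_domain_error")
  expect_error(replicate_stats(c(-2, 1)), class = "stripwave_domain_error")
})

test_that("replicate statistics match a brute-force oracle and scale invariance", {
  set.seed(88)
  for (i in 1:20) {
    v <- abs(rnorm(sample(2:12, 1), mean = 5))
    st <- replicate_stats(v)
    or <- stats_oracle(v)
    expect_equal(st$mean, or$mean, tolerance = 1e-12)
    expect_equal(st$sd, or$sd, tolerance = 1e-12)
    expect_equal(st$cv, or$cv, tolerance = 1e-12)
    expect_equal(replicate_stats(3.14 * v)$cv, st$cv, tolerance = 1e-12)
  }
})

test_that("LOD rule flags detectability against blank + k*SD", {
  r <- lod_assess(c(0, 0, 0), list("1" = c(1, 1, 1)), k = 3)
  expect_true(all(r$detectable))
  expect_equal(r$lod, 1)
  r2 <- lod_assess(c(0.5, 0.5), list("1" = c(0.5, 0.5)), k = 1)
  expect_false(any(r2$detectable))
  expect_true(is.na(r2$lod))
  expect_error(lod_assess(numeric(0), list("1" = 1)), class = "stripwave_domain_error")
})

test_that("LOD on the bundled detection-limit table matches the instrument call", {
  lod_tab <- reference_tables()$lod
  blanks <- lod_tab$characteristic_value[lod_tab$concentration_ng_ml == 0]
  levels <- split(lod_tab$characteristic_value[lod_tab$concentration_ng_ml > 0],
                  lod_tab$concentration_ng_ml[lod_tab$concentration_ng_ml > 0])
  # single blank value: SD 0, so any level above the blank mean is detectable
  r <- lod_assess(blanks, levels, k = 3)
  expect_equal(r$lod, 0.05)
})
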