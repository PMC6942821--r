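test_that("standard test signals are deterministic with the stated shapes", {
  h <- test_signal("heavisine", 1024)
  expect_equal(h$n, 1024)
  expect_identical(h$intensities, test_signal("heavisine", 1024)$intensities)
  # blocks: piecewise constant with at most 11 breakpoints
  b <- test_signal("blocks", 1024)
  expect_lte(sum(abs(diff(b$intensities)) > 1e-12), 11)
  for (nm in c("bumps", "doppler")) expect_equal(test_signal(nm, 256)$n, 256)
  expect_error(test_signal("square", 128), class = "stripwave_config_error")
  expect_error(test_signal("blocks", 32), class = "stripwave_domain_error")
})

test_that("add_noise is seeded, unbiased in SD, and leaves the RNG alone", {
  x <- strip_signal(rep(0, 1e5))
  expect_identical(add_noise(x, 0, seed = 1)$intensities, x$intensities)
  n1 <- add_noise(x, 2, seed = 4)$intensities
  expect_identical(n1, add_noise(x, 2, seed = 4)$intensities)
  expect_false(identical(n1, add_noise(x, 2, seed = 5)$intensities))
  expect_equal(sd(n1), 2, tolerance = 0.02)
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(add_noise(x, 1, seed = 77)); after <- rnorm(3)
  expect_identical(before, after)
  expect_error(add_noise(x, -1), class = "stripwave_domain_error")
})

test_that("simulate_scan honors its truth and is deterministic", {
  tr <- scan_truth(t_amplitude = 0, noise_sigma = 0)
  s <- simulate_scan(tr)
  expect_equal(s$positions[which.max(s$intensities)], tr$c_position,
               tolerance = 0.05)
  tr2 <- scan_truth(concentration = 50, noise_sigma = 150, seed = 8)
  expect_identical(simulate_scan(tr2)$intensities, simulate_scan(tr2)$intensities)
  expect_error(scan_truth(c_position = 16, t_position = 15),
               class = "stripwave_config_error")
})

test_that("band values recover the closed-form Gaussian integrals at zero noise", {
  tr <- scan_truth(concentration = 20, noise_sigma = 0)
  s <- simulate_scan(tr)
  windows <- locate_bands(s, band_layout())
  corrected <- baseline_correct(s, windows)
  c_val <- band_value(corrected, windows$c_window)
  t_val <- band_value(corrected, windows$t_window)
  # +/- 3 SD window holds erf(3/sqrt(2)) = 99.73% of the full integral
  trunc <- 2 * pnorm(3) - 1
  expect_equal(c_val, tr$c_amplitude * tr$band_width * sqrt(2 * pi) * trunc,
               tolerance = 0.005)
  expect_equal(t_val / c_val, tr$t_amplitude / tr$c_amplitude, tolerance = 1e-4)
})

test_that("dilution series: exact linearity at zero noise, recovery under noise", {
  single <- simulate_dilution_series(5, replicates = 1)
  expect_length(single, 1)
  concs <- c(0, 1, 10, 100)
  series <- simulate_dilution_series(concs, replicates = 1, noise_sigma = 0,
                                     c_jitter = 0)
  chars <- vapply(series, function(s)
    quantify(s$signal, layout = fixed_layout(), denoise = FALSE)$characteristic_value, 1.0)
  fit <- fit_calibration(data.frame(concentration = concs,
                                    characteristic_value = chars))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.0065, tolerance = 1e-6)
  # monotone in concentration at zero noise
  expect_true(all(diff(chars) > 0))
  # determinism of the whole series
  s1 <- simulate_dilution_series(concs, replicates = 2, seed = 31)
  s2 <- simulate_dilution_series(concs, replicates = 2, seed = 31)
  expect_identical(lapply(s1, function(s) s$signal$intensities),
                   lapply(s2, function(s) s$signal$intensities))
})

test_that("response models are monotone and validated", {
  m <- response_model()
  expect_true(all(diff(response_value(m, c(0, 0.1, 1, 10, 100))) > 0))
  msat <- response_model("saturating", vmax = 0.8, k_half = 20)
  v <- response_value(msat, c(0, 1, 10, 100, 1000))
  expect_true(all(diff(v) > 0))
  expect_lt(v[5], 0.8 + msat$background)
  expect_error(response_model(slope = -1), class = "stripwave_config_error")
  expect_error(response_value(m, -1), class = "stripwave_domain_error")
})
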