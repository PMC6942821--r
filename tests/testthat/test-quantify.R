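make_scan <- function(concentration = 20, noise_sigma = 0, seed = 1, ...) {
  simulate_scan(scan_truth(concentration = concentration,
                           noise_sigma = noise_sigma, seed = seed, ...))
}

test_that("auto localization finds both bands near their true centers", {
  s <- make_scan()
  w <- locate_bands(s, band_layout())
  expect_equal(mean(w$c_window), 25, tolerance = 0.1)
  expect_equal(mean(w$t_window), 15, tolerance = 0.1)
})

test_that("a control-only scan is an invalid strip; fixed mode echoes windows", {
  s <- simulate_scan(scan_truth(t_amplitude = 0, noise_sigma = 0))
  expect_error(locate_bands(s, band_layout()), class = "stripwave_invalid_strip")
  lay <- fixed_layout()
  w <- locate_bands(make_scan(), lay)
  expect_identical(w$c_window, lay$c_window)
  expect_identical(w$t_window, lay$t_window)
  bad <- band_layout(mode = "fixed", c_window = c(40, 60), t_window = c(12, 18))
  expect_error(locate_bands(make_scan(), bad), class = "stripwave_config_error")
})

test_that("baseline correction zeroes the off-band region and is idempotent", {
  s <- make_scan()
  w <- locate_bands(s, band_layout())
  corr <- baseline_correct(s, w)
  off <- corr$positions < 8 | (corr$positions > 32)
  expect_lt(abs(mean(corr$intensities[off])), 1e-6 * max(s$intensities))
  corr2 <- baseline_correct(corr, w)
  expect_equal(corr2$intensities, corr$intensities, tolerance = 1e-8)
})

test_that("baseline tilt does not bias band integrals", {
  flat <- simulate_scan(scan_truth(concentration = 20, noise_sigma = 0,
                                   baseline_slope = 0))
  tilted <- simulate_scan(scan_truth(concentration = 20, noise_sigma = 0,
                                     baseline_slope = 25))
  w <- locate_bands(flat, band_layout())
  v_flat <- band_value(baseline_correct(flat, w), w$c_window)
  v_tilt <- band_value(baseline_correct(tilted, w), w$c_window)
  expect_equal(v_tilt, v_flat, tolerance = 1e-3)
})

test_that("band_value modes behave on canonical inputs", {
  p <- seq(0, 10, length.out = 501)
  gauss <- strip_signal(exp(-(p - 5)^2 / (2 * 0.8^2)), positions = p)
  expect_equal(band_value(gauss, c(5 - 3 * 0.8, 5 + 3 * 0.8)),
               0.8 * sqrt(2 * pi), tolerance = 0.005)
  expect_equal(band_value(gauss, c(2, 8), mode = "height"), 1, tolerance = 1e-3)
  zero <- strip_signal(rep(0, 100))
  expect_equal(band_value(zero, c(10, 20)), 0)
  expect_error(band_value(zero, c(200, 210)), class = "stripwave_domain_error")
})

test_that("characteristic value reproduces the instrument worked examples", {
  # printed ratios reproduce from the printed integer counts to 6-7 s.f.
  expect_equal(characteristic_value(13392, 20244), 0.661529362, tolerance = 1e-6)
  expect_equal(characteristic_value(2747, 26454), 0.103840627, tolerance = 1e-6)
  expect_equal(characteristic_value(0, 20000), 0)
  expect_error(characteristic_value(10, 0), class = "stripwave_invalid_strip")
  expect_error(characteristic_value(-1, 10), class = "stripwave_domain_error")
})

test_that("quantify recovers the true ratio and tolerates denoising on clean data", {
  s <- simulate_scan(scan_truth(t_amplitude = 15000, noise_sigma = 0))
  q_raw <- quantify(s, denoise = FALSE)
  expect_equal(q_raw$characteristic_value, 0.5, tolerance = 1e-3)
  q_dn <- quantify(s, denoise = TRUE)
  expect_equal(q_dn$characteristic_value, q_raw$characteristic_value,
               tolerance = 1e-3)
  expect_s3_class(q_dn$plan, "threshold_plan")
  expect_null(q_raw$plan)
})

test_that("characteristic value is invariant to gain and offset", {
  s <- make_scan(noise_sigma = 200, seed = 12)
  for (mode in c("area", "height")) {
    q <- quantify(s, layout = fixed_layout(), denoise = FALSE, mode = mode)
    scaled <- with(s, strip_signal(3.7 * s$intensities, positions = s$positions))
    q_scaled <- quantify(scaled, layout = fixed_layout(), denoise = FALSE, mode = mode)
    expect_equal(q_scaled$characteristic_value, q$characteristic_value,
                 tolerance = 1e-9, label = paste("gain", mode))
    shifted <- strip_signal(s$intensities + 5000, positions = s$positions)
    q_shift <- quantify(shifted, layout = fixed_layout(), denoise = FALSE, mode = mode)
    expect_equal(q_shift$characteristic_value, q$characteristic_value,
                 tolerance = 1e-6, label = paste("offset", mode))
  }
})

test_that("noisy quantification recovers the truth ratio on a mid-range strip", {
  # noise at 10% of the control amplitude; a mid-range T band keeps the
  # per-replicate ratio CV near 6%, so 50 seeds resolve a 2% bias bound
  chars <- vapply(1:50, function(i) {
    s <- simulate_scan(scan_truth(t_amplitude = 15000, noise_sigma = 3000,
                                  seed = i))
    quantify(s, layout = fixed_layout(), denoise = FALSE)$characteristic_value
  }, 1.0)
  expect_equal(mean(chars), 0.5, tolerance = 0.02)
  chars_dn <- vapply(1:50, function(i) {
    s <- simulate_scan(scan_truth(t_amplitude = 15000, noise_sigma = 3000,
                                  seed = i))
    quantify(s, layout = fixed_layout())$characteristic_value
  }, 1.0)
  expect_equal(mean(chars_dn), 0.5, tolerance = 0.02)
})
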