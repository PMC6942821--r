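test_that("universal threshold matches its closed form and edge cases", {
  expect_equal(threshold_universal(0, 1000), 0)
  expect_equal(threshold_universal(1, 1), 0)
  expect_equal(threshold_universal(2, 1024), 2 * sqrt(2 * log(1024)),
               tolerance = 1e-12)
  expect_equal(threshold_universal(2, 1024), 7.4465955, tolerance = 1e-6)
  expect_error(threshold_universal(-1, 10), class = "stripwave_domain_error")
  expect_error(threshold_universal(1, 0), class = "stripwave_domain_error")
})

test_that("level-dependent threshold matches its closed form and decreases in j", {
  # frozen from the closed form sigma*sqrt(2 ln N)/ln(e + j)
  expect_equal(threshold_level(1, 1024, 1), 2.8351527, tolerance = 1e-6)
  expect_equal(threshold_level(1, 1024, 2), 2.3998905, tolerance = 1e-6)
  expect_equal(threshold_level(0, 512, 3), 0)
  t_seq <- threshold_level(1.7, 900, 1:6)
  expect_true(all(diff(t_seq) < 0))
  expect_error(threshold_level(1, 10, 0), class = "stripwave_domain_error")
  expect_error(threshold_level(-1, 10, 1), class = "stripwave_domain_error")
})

test_that("hard, soft and improved rules reproduce their worked examples", {
  expect_equal(threshold_hard(5, 2), 5)
  expect_equal(threshold_hard(1.5, 2), 0)
  expect_equal(threshold_hard(-3, 2), -3)

  expect_equal(threshold_soft(5, 2), 3)
  expect_equal(threshold_soft(-5, 2), -3)
  expect_equal(threshold_soft(2, 2), 0)

  expect_equal(threshold_improved(2, 2), 0)
  expect_equal(threshold_improved(3, 2), 2)          # 3 - 2/(1 + log2(2))
  expect_equal(threshold_improved(-3, 2), -2)
  expect_equal(threshold_improved(1026, 2), 1025.8182, tolerance = 1e-7)

  for (fn in list(threshold_hard, threshold_soft, threshold_improved))
    expect_error(fn(1, -0.5), class = "stripwave_domain_error")
})

test_that("threshold functions satisfy sandwich, oddness, continuity, asymptote", {
  t <- 2.3
  xs <- c(seq(-10, 10, by = 0.037), t + c(-1e-9, 0, 1e-9), -t + c(-1e-9, 0, 1e-9))
  h <- threshold_hard(xs, t); s <- threshold_soft(xs, t); im <- threshold_improved(xs, t)
  expect_true(all(abs(s) <= abs(im) + 1e-12))
  expect_true(all(abs(im) <= abs(h) + 1e-12))
  # odd symmetry
  expect_equal(threshold_hard(-xs, t), -h)
  expect_equal(threshold_soft(-xs, t), -s)
  expect_equal(threshold_improved(-xs, t), -im)
  # continuity of soft and improved at |x| = t
  for (fn in list(threshold_soft, threshold_improved)) {
    expect_lt(abs(fn(t + 1e-9, t) - fn(t - 1e-9, t)), 1e-6)
    expect_lt(abs(fn(-t - 1e-9, t) - fn(-t + 1e-9, t)), 1e-6)
  }
  # hard-threshold asymptote of the improved rule: the residual
  # t / (1 + log2(1 + |x| - t)) decays to zero, monotonically in |x|
  res <- function(x) abs(threshold_improved(x, 2) - x)
  expect_true(res(10) > res(1e3) && res(1e3) > res(1e6))
  expect_lt(res(1e6), 0.1)
  expect_lt(res(1e6) / 1e6, 1e-7)
})

test_that("noise SD estimator is the MAD rule and is consistent", {
  expect_equal(estimate_noise_sigma(rep(0, 8)), 0)
  expect_equal(estimate_noise_sigma(c(-0.6745, 0.6745, 0.6745, -0.6745)), 1)
  expect_error(estimate_noise_sigma(numeric(0)), class = "stripwave_domain_error")
  # finest detail band of unit white noise: estimator within 2% of 1
  noise <- add_noise(strip_signal(rep(0, 1e5)), sigma = 1, seed = 99)
  d1 <- dwt_decompose(noise, levels = 1)$details[[1]]
  expect_equal(estimate_noise_sigma(d1), 1, tolerance = 0.02)
})
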