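# Shared fixtures and independent oracles.

# Fixed-window layout matching the default simulated scan geometry
# (T line at 15 mm, C line at 25 mm, band SD 1 mm).
fixed_layout <- function() {
  band_layout(mode = "fixed", t_window = c(12, 18), c_window = c(22, 28))
}

# Bundled linearity table as calibration points.
linearity_points <- function() {
  ref <- reference_tables()$linearity
  data.frame(concentration = ref$concentration_ng_ml,
             characteristic_value = ref$characteristic_value)
}

# Independent OLS oracle: closed-form normal equations, no lm machinery.
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(resid^2) / sum((y - yb)^2))
}

# Independent two-pass mean/SD oracle for replicate statistics.
stats_oracle <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  list(mean = m, sd = s, cv = s / m)
}
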