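# Shrinkage rules and threshold selectors.
#
# Three coefficient rules: hard (keep-or-kill), soft (shrink by t), and an
# improved rule that shrinks by t / (1 + log2(1 + |x| - t)) so it is
# continuous at |x| = t like soft thresholding yet approaches the identity
# for large coefficients like hard thresholding.

check_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop_domain("threshold 't' must be a single finite value >= 0")
  t
}

#' Hard threshold rule
#'
#' Keeps coefficients whose magnitude exceeds the threshold and zeroes the
#' rest.
#'
#' @param x Numeric vector of wavelet coefficients.
#' @param t Threshold, `t >= 0`.
#' @return Thresholded coefficients, same length as `x`.
#' @family threshold functions
#' @export
threshold_hard <- function(x, t) {
  check_threshold(t)
  ifelse(abs(x) > t, x, 0)
}

#' Soft threshold rule
#'
#' Shrinks surviving coefficients toward zero by the full threshold:
#' `sign(x) * (|x| - t)` where `|x| > t`, zero elsewhere. Continuous in `x`
#' but biased for large coefficients.
#'
#' @inheritParams threshold_hard
#' @return Thresholded coefficients.
#' @family threshold functions
#' @export
threshold_soft <- function(x, t) {
  check_threshold(t)
  ifelse(abs(x) > t, sign(x) * (abs(x) - t), 0)
}

#' Improved threshold rule
#'
#' Interpolates between soft and hard thresholding: surviving coefficients
#' are shrunk by `t / (1 + log2(1 + |x| - t))`, which equals `t` at
#' `|x| = t` (so the rule is continuous, like soft) and decays to zero as
#' `|x|` grows (so the rule is asymptotically unbiased, like hard). For all
#' `x`, `|threshold_soft(x, t)| <= |threshold_improved(x, t)| <=
#' |threshold_hard(x, t)|`.
#'
#' @inheritParams threshold_hard
#' @return Thresholded coefficients.
#' @family threshold functions
#' @export
threshold_improved <- function(x, t) {
  check_threshold(t)
  excess <- abs(x) - t
  shrink <- t / (1 + log2(1 + pmax(excess, 0)))
  ifelse(abs(x) >= t, sign(x) * (abs(x) - shrink), 0)
}

.threshold_functions <- list(hard = threshold_hard, soft = threshold_soft,
                             improved = threshold_improved)

threshold_function <- function(name) {
  fn <- .threshold_functions[[name]]
  if (is.null(fn))
    stop_config(sprintf("unknown threshold function '%s' (hard, soft, improved)", name))
  fn
}

#' Universal (VisuShrink) threshold
#'
#' The global threshold `sigma * sqrt(2 * ln(n))`, near-minimax for white
#' Gaussian noise of standard deviation `sigma` over `n` samples.
#'
#' @param sigma Noise standard deviation, `>= 0`.
#' @param n Sample count, `>= 1`.
#' @return Threshold value (0 when `sigma = 0` or `n = 1`).
#' @family threshold selectors
#' @export
threshold_universal <- function(sigma, n) {
  check_scalar(sigma, "sigma"); check_scalar(n, "n")
  if (sigma < 0) stop_domain("'sigma' must be >= 0")
  if (n < 1) stop_domain("'n' must be >= 1")
  sigma * sqrt(2 * log(n))
}

#' Level-dependent threshold
#'
#' Scales the universal threshold down with the decomposition level:
#' `sigma_j * sqrt(2 * ln(n_j)) / ln(e + j)`. Because noise energy
#' concentrates at fine scales, the divisor makes the threshold strictly
#' decrease as `j` (here 1 = finest detail band) increases, protecting
#' coarse-scale signal structure.
#'
#' @param sigma_j Noise standard deviation of the level-`j` detail band.
#' @param n_j Number of coefficients in that band, `>= 1`.
#' @param j Level index, `>= 1`; `j = 1` is the finest scale. Vectorized.
#' @return Threshold value(s).
#' @family threshold selectors
#' @export
threshold_level <- function(sigma_j, n_j, j) {
  check_scalar(sigma_j, "sigma_j"); check_scalar(n_j, "n_j")
  if (sigma_j < 0) stop_domain("'sigma_j' must be >= 0")
  if (n_j < 1) stop_domain("'n_j' must be >= 1")
  if (!is.numeric(j) || length(j) < 1L || any(!is.finite(j)) || any(j < 1))
    stop_domain("'j' must be >= 1")
  sigma_j * sqrt(2 * log(n_j)) / log(exp(1) + j)
}

#' Robust noise standard deviation from detail coefficients
#'
#' The median absolute deviation estimator `median(|d|) / 0.6745`,
#' consistent for the SD of Gaussian noise when the clean signal's
#' coefficients are sparse (as in the finest detail band).
#'
#' @param detail_coeffs Nonempty numeric vector of detail coefficients.
#' @return Estimated noise SD.
#' @export
estimate_noise_sigma <- function(detail_coeffs) {
  if (!is.numeric(detail_coeffs) || length(detail_coeffs) < 1L)
    stop_domain("'detail_coeffs' must be a nonempty numeric vector")
  stats::median(abs(detail_coeffs)) / 0.6745
}

# Per-level thresholds for a decomposition, with provenance for audit.
# rule "universal": one global threshold from the finest band's sigma,
# applied to every detail band. rule "level_dependent": per-band sigma and
# the level-scaled selector.
threshold_plan <- function(decomp, rule = c("level_dependent", "universal"),
                           sigma = NULL) {
  rule <- match.arg(rule)
  n_bands <- decomp$levels
  band_lengths <- vapply(decomp$details, length, 1L)
  sigmas <- if (!is.null(sigma)) {
    check_scalar(sigma, "sigma")
    if (sigma < 0) stop_domain("'sigma' must be >= 0")
    rep(sigma, n_bands)
  } else if (rule == "universal") {
    rep(estimate_noise_sigma(decomp$details[[1L]]), n_bands)
  } else {
    vapply(decomp$details, estimate_noise_sigma, 1.0)
  }
  thresholds <- if (rule == "universal") {
    rep(threshold_universal(sigmas[1L], decomp$n), n_bands)
  } else {
    vapply(seq_len(n_bands), function(j)
      threshold_level(sigmas[j], band_lengths[j], j), 1.0)
  }
  structure(
    list(rule = rule, sigma_estimates = sigmas, thresholds = thresholds,
         band_lengths = band_lengths, levels = n_bands),
    class = "threshold_plan"
  )
}

#' @export
print.threshold_plan <- function(x, ...) {
  cat(sprintf("<threshold_plan> rule=%s\n", x$rule))
  print(data.frame(level = seq_len(x$levels), n_coeff = x$band_lengths,
                   sigma = x$sigma_estimates, threshold = x$thresholds),
        row.names = FALSE)
  invisible(x)
}
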