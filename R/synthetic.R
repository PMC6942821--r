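# Synthetic data: standard shrinkage test signals and strip-scan fixtures
# with known ground truth. Every generator is a pure function of its
# arguments including the seed; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Standard piecewise-smooth test signals
#'
#' The four classical wavelet-shrinkage benchmark signals (blocks, bumps,
#' heavisine, doppler), sampled at `t = (1:n)/n` in their standard
#' amplitudes. Deterministic closed forms.
#'
#' @param name One of `"blocks"`, `"bumps"`, `"heavisine"`, `"doppler"`.
#' @param n Number of samples, `>= 64`.
#' @return A [strip_signal] of length `n`.
#' @export
test_signal <- function(name = c("blocks", "bumps", "heavisine", "doppler"),
                        n = 1024L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("blocks", "bumps", "heavisine", "doppler"))
    stop_config("unknown test signal (blocks, bumps, heavisine, doppler)")
  check_scalar(n, "n")
  if (n < 64) stop_domain("'n' must be >= 64")
  t <- (1:n) / n
  pos <- c(0.1, 0.13, 0.15, 0.23, 0.25, 0.40, 0.44, 0.65, 0.76, 0.78, 0.81)
  x <- switch(name,
    blocks = {
      h <- c(4, -5, 3, -4, 5, -4.2, 2.1, 4.3, -3.1, 2.1, -4.2)
      # right-continuous step keeps the signal exactly piecewise constant
      # even when a breakpoint falls on the sampling grid
      rowSums(sapply(seq_along(pos), function(j) h[j] * (t >= pos[j])))
    },
    bumps = {
      h <- c(4, 5, 3, 4, 5, 4.2, 2.1, 4.3, 3.1, 5.1, 4.2)
      w <- c(0.005, 0.005, 0.006, 0.01, 0.01, 0.03, 0.01, 0.01, 0.005, 0.008, 0.005)
      rowSums(sapply(seq_along(pos), function(j)
        h[j] * (1 + abs((t - pos[j]) / w[j]))^-4))
    },
    heavisine = 4 * sin(4 * pi * t) - sign(t - 0.3) - sign(0.72 - t),
    doppler = sqrt(t * (1 - t)) * sin(2 * pi * 1.05 / (t + 0.05))
  )
  strip_signal(as.numeric(x))
}

#' Add white Gaussian noise to a signal
#'
#' @param signal A [strip_signal] or numeric vector.
#' @param sigma Noise SD, `>= 0`.
#' @param seed Integer seed; the draw is deterministic given the seed and
#'   the global RNG state is restored afterwards.
#' @return A [strip_signal] with i.i.d. `N(0, sigma^2)` noise added.
#' @export
add_noise <- function(signal, sigma, seed = 1L) {
  signal <- as_strip_signal(signal)
  check_scalar(sigma, "sigma")
  if (sigma < 0) stop_domain("'sigma' must be >= 0")
  if (sigma == 0) return(signal)
  noise <- with_seed(seed, stats::rnorm(signal$n, sd = sigma))
  with_intensities(signal, signal$intensities + noise)
}

#' Concentration-response model for the test band
#'
#' Maps analyte concentration (ng/ml) to the expected characteristic value
#' (T/C ratio). The default linear model (slope 0.0065 per ng/ml,
#' background 0.01) spans roughly 0.01-0.66 over 0-100 ng/ml, the range a
#' europium-chelate lateral-flow assay covers across its calibration
#' dilutions. The saturating form is a one-site binding curve
#' `background + vmax * c / (k_half + c)`.
#'
#' @param kind `"linear"` or `"saturating"`.
#' @param slope Characteristic value per ng/ml (linear model).
#' @param background Characteristic value at zero concentration, `>= 0`
#'   (nonspecific binding).
#' @param vmax,k_half Saturating-model plateau rise and half-saturation
#'   concentration.
#' @return An object of class `response_model`.
#' @export
response_model <- function(kind = c("linear", "saturating"), slope = 0.0065,
                           background = 0.01, vmax = 1, k_half = 50) {
  kind <- match.arg(kind)
  check_scalar(background, "background")
  if (background < 0) stop_config("'background' must be >= 0")
  if (kind == "linear") {
    check_scalar(slope, "slope")
    if (slope < 0) stop_config("'slope' must be >= 0 (response is non-decreasing)")
  } else {
    check_scalar(vmax, "vmax"); check_scalar(k_half, "k_half")
    if (vmax < 0 || k_half <= 0) stop_config("'vmax' >= 0 and 'k_half' > 0 required")
  }
  structure(list(kind = kind, slope = slope, background = background,
                 vmax = vmax, k_half = k_half),
            class = "response_model")
}

#' Expected characteristic value at a concentration
#'
#' @param model A [response_model()].
#' @param concentration Concentration(s) in ng/ml, `>= 0`. Vectorized.
#' @return Expected characteristic value(s).
#' @export
response_value <- function(model, concentration) {
  if (!inherits(model, "response_model")) stop_domain("expected a response_model")
  if (any(concentration < 0)) stop_domain("'concentration' must be >= 0")
  if (model$kind == "linear") model$background + model$slope * concentration
  else model$background + model$vmax * concentration / (model$k_half + concentration)
}

#' Ground truth for one simulated strip scan
#'
#' Describes everything [simulate_scan()] needs: band geometry, amplitudes,
#' baseline and noise. The test-band amplitude is tied to the control-band
#' amplitude through the response model, so the true characteristic value
#' of the scan is exactly `response_value(response, concentration)`.
#'
#' Default geometry: a 40 mm read window sampled at 512 points, test line
#' at 15 mm and control line at 25 mm (10 mm apart, i.e. 10 band SDs),
#' Gaussian band SD 1 mm, baseline 200 counts with a 2 count/mm tilt, and
#' control amplitude 30000 counts - magnitudes in line with the
#' tens-of-thousands count scale of fluorescence strip readers.
#'
#' @param concentration Analyte concentration in ng/ml, `>= 0`.
#' @param response A [response_model()] linking concentration to T/C.
#' @param t_amplitude Optional explicit test-band peak amplitude; overrides
#'   the response model.
#' @param c_position,t_position Band centers (mm); must be at least
#'   `4 * band_width` apart and inside the scan range.
#' @param c_amplitude Control-band peak amplitude (counts), `>= 0`.
#' @param band_width Gaussian SD of both bands (mm).
#' @param baseline_level,baseline_slope Baseline intercept (counts) and
#'   tilt (counts/mm).
#' @param noise_sigma White-noise SD (counts), default 300 (1% of the
#'   default control amplitude).
#' @param seed Integer seed for the noise draw.
#' @param n Samples per scan.
#' @param scan_length Read window length (mm).
#' @return An object of class `scan_truth`.
#' @export
scan_truth <- function(concentration = 0, response = response_model(),
                       t_amplitude = NULL,
                       c_position = 25, t_position = 15, c_amplitude = 30000,
                       band_width = 1, baseline_level = 200,
                       baseline_slope = 2, noise_sigma = 300, seed = 1L,
                       n = 512L, scan_length = 40) {
  check_scalar(concentration, "concentration")
  if (concentration < 0) stop_domain("'concentration' must be >= 0")
  for (nm in c("c_position", "t_position", "c_amplitude", "band_width",
               "baseline_level", "baseline_slope", "noise_sigma",
               "scan_length"))
    check_scalar(get(nm), nm)
  if (c_amplitude < 0) stop_config("'c_amplitude' must be >= 0")
  if (band_width <= 0) stop_config("'band_width' must be > 0")
  if (noise_sigma < 0) stop_domain("'noise_sigma' must be >= 0")
  if (min(c_position, t_position) < 0 ||
      max(c_position, t_position) > scan_length)
    stop_config("band positions must lie within the scan range")
  if (abs(c_position - t_position) < 4 * band_width)
    stop_config("bands overlap: centers must be >= 4 band widths apart")
  if (is.null(t_amplitude)) {
    t_amplitude <- response_value(response, concentration) * c_amplitude
  }
  check_scalar(t_amplitude, "t_amplitude")
  if (t_amplitude < 0) stop_config("'t_amplitude' must be >= 0")
  structure(
    list(concentration = concentration, c_position = c_position,
         t_position = t_position, c_amplitude = c_amplitude,
         t_amplitude = t_amplitude, band_width = band_width,
         baseline_level = baseline_level, baseline_slope = baseline_slope,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         n = as.integer(n), scan_length = scan_length),
    class = "scan_truth"
  )
}

#' Simulate one strip-reader line scan
#'
#' Baseline + tilt + two Gaussian bands + white Gaussian noise:
#' `baseline_level + baseline_slope * p + A_c * exp(-(p - p_c)^2 / (2 w^2))
#' + A_t * exp(-(p - p_t)^2 / (2 w^2)) + N(0, sigma^2)`.
#'
#' @param truth A [scan_truth()].
#' @return A [strip_signal]; the truth object is attached as attribute
#'   `"truth"`.
#' @export
simulate_scan <- function(truth) {
  if (!inherits(truth, "scan_truth")) stop_domain("expected a scan_truth")
  p <- seq(0, truth$scan_length, length.out = truth$n)
  band <- function(center, amp)
    amp * exp(-(p - center)^2 / (2 * truth$band_width^2))
  y <- truth$baseline_level + truth$baseline_slope * p +
    band(truth$c_position, truth$c_amplitude) +
    band(truth$t_position, truth$t_amplitude)
  if (truth$noise_sigma > 0)
    y <- y + with_seed(truth$seed, stats::rnorm(truth$n, sd = truth$noise_sigma))
  out <- strip_signal(y, positions = p)
  attr(out, "truth") <- truth
  out
}

#' Simulate a dilution series of strip scans
#'
#' One scan per (concentration, replicate), emulating a calibration run.
#' The control-band amplitude gets small multiplicative lot-to-lot jitter
#' (5% SD by default); the test-band amplitude follows the response model.
#' Scan seeds are derived deterministically from `seed`.
#'
#' @param concentrations Numeric vector of concentrations (ng/ml), `>= 0`.
#' @param model A [response_model()].
#' @param replicates Replicate scans per concentration, `>= 1`.
#' @param noise_sigma White-noise SD (counts) for every scan.
#' @param seed Integer master seed.
#' @param c_jitter SD of the multiplicative control-amplitude jitter.
#' @param ... Further arguments passed to [scan_truth()] (geometry etc.).
#' @return List of elements, each a list with `signal` and `truth`.
#' @export
simulate_dilution_series <- function(concentrations, model = response_model(),
                                     replicates = 3L, noise_sigma = 300,
                                     seed = 1L, c_jitter = 0.05, ...) {
  if (length(concentrations) < 1L || any(concentrations < 0))
    stop_domain("'concentrations' must be nonempty and >= 0")
  if (replicates < 1) stop_domain("'replicates' must be >= 1")
  grid <- expand.grid(rep = seq_len(replicates), conc = concentrations)
  jitters <- with_seed(seed, stats::rnorm(nrow(grid), mean = 1, sd = c_jitter))
  lapply(seq_len(nrow(grid)), function(i) {
    truth <- scan_truth(concentration = grid$conc[i], response = model,
                        c_amplitude = 30000 * max(jitters[i], 0.5),
                        noise_sigma = noise_sigma,
                        seed = (seed + 7919L * i) %% .Machine$integer.max, ...)
    list(signal = simulate_scan(truth), truth = truth)
  })
}
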