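# Band quantification: locate the control (C) and test (T) lines on a
# scan, correct the baseline, reduce each band to a scalar intensity, and
# form the T/C characteristic value.

#' Band layout for quantification
#'
#' Either fixed windows (mm) for both bands, or automatic localization of
#' the two most prominent peaks.
#'
#' @param mode `"auto_locate"` or `"fixed"`.
#' @param c_window,t_window Numeric `c(start, end)` windows in mm
#'   (half-open, `[start, end)`); required for `mode = "fixed"`.
#' @param band_width Assumed Gaussian band SD (mm); auto windows extend
#'   +/- 3 band widths around each located peak.
#' @param min_separation Minimum peak separation (mm) in auto mode.
#' @param c_side Which side of the scan carries the control line in auto
#'   mode: `"right"` (downstream, default) or `"left"`.
#' @param prominence Minimum peak height above the local baseline, as a
#'   fraction of the tallest peak's height (default 0.02). Fewer than two
#'   peaks above this floor is an invalid strip (missing control line).
#' @return An object of class `band_layout`.
#' @export
band_layout <- function(mode = c("auto_locate", "fixed"), c_window = NULL,
                        t_window = NULL, band_width = 1, min_separation = 4,
                        c_side = c("right", "left"), prominence = 0.02) {
  mode <- match.arg(mode)
  c_side <- match.arg(c_side)
  check_scalar(band_width, "band_width")
  check_scalar(min_separation, "min_separation")
  check_scalar(prominence, "prominence")
  if (band_width <= 0 || min_separation <= 0 || prominence < 0 || prominence > 1)
    stop_config("invalid band_layout parameters")
  if (mode == "fixed") {
    for (w in list(c_window, t_window)) {
      if (is.null(w) || length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
        stop_config("fixed mode requires c_window and t_window as c(start, end)")
    }
    if (max(min(c_window[2], t_window[2]) - max(c_window[1], t_window[1]), 0) > 0)
      stop_config("c_window and t_window must be disjoint")
  }
  structure(list(mode = mode, c_window = c_window, t_window = t_window,
                 band_width = band_width, min_separation = min_separation,
                 c_side = c_side, prominence = prominence),
            class = "band_layout")
}

# Local maxima of y (interior strict-rise, non-fall points); returns indices.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Locate the control and test bands
#'
#' Fixed mode echoes the configured windows. Auto mode detrends the scan
#' with a line through its end regions, finds the two tallest local maxima
#' separated by at least `min_separation`, and returns +/- 3 band-width
#' windows; the peak nearer the configured control side is the C band.
#'
#' @param scan A [strip_signal].
#' @param layout A [band_layout()].
#' @return List with `c_window` and `t_window`, each `c(start, end)` in mm.
#' @export
locate_bands <- function(scan, layout = band_layout()) {
  scan <- as_strip_signal(scan)
  if (!inherits(layout, "band_layout")) stop_config("'layout' must be a band_layout")
  if (layout$mode == "fixed") {
    rng <- range(scan$positions)
    for (w in list(layout$c_window, layout$t_window))
      if (w[1] < rng[1] || w[2] > rng[2])
        stop_config("fixed windows must lie within the scan range")
    return(list(c_window = layout$c_window, t_window = layout$t_window))
  }
  p <- scan$positions
  y <- scan$intensities
  n <- scan$n
  # crude detrend for peak picking: line through the means of the outer 10%
  k <- max(2L, floor(n * 0.1))
  edge_x <- c(mean(p[1:k]), mean(p[(n - k + 1):n]))
  edge_y <- c(mean(y[1:k]), mean(y[(n - k + 1):n]))
  slope <- (edge_y[2] - edge_y[1]) / (edge_x[2] - edge_x[1])
  yd <- y - (edge_y[1] + slope * (p - edge_x[1]))
  peaks <- local_maxima(yd)
  if (length(peaks) > 0) {
    floor_h <- layout$prominence * max(yd[peaks])
    peaks <- peaks[yd[peaks] > 0 & yd[peaks] >= floor_h]
  }
  peaks <- peaks[order(yd[peaks], decreasing = TRUE)]
  chosen <- integer(0)
  for (pk in peaks) {
    if (all(abs(p[pk] - p[chosen]) >= layout$min_separation)) chosen <- c(chosen, pk)
    if (length(chosen) == 2L) break
  }
  if (length(chosen) < 2L)
    stop_invalid_strip("fewer than two bands found: missing test or control line")
  pos <- sort(p[chosen])
  c_pos <- if (layout$c_side == "right") pos[2] else pos[1]
  t_pos <- if (layout$c_side == "right") pos[1] else pos[2]
  half <- 3 * layout$band_width
  clamp <- function(w) c(max(w[1], p[1]), min(w[2], p[n]))
  list(c_window = clamp(c(c_pos - half, c_pos + half)),
       t_window = clamp(c(t_pos - half, t_pos + half)))
}

in_window <- function(positions, window) {
  positions >= window[1] & positions < window[2]
}

#' Subtract a linear baseline fitted to off-band samples
#'
#' Fits `intensity ~ position` by least squares over all samples outside
#' both band windows and subtracts the fitted line, so the off-band
#' residual mean is zero and band integrals are freed of baseline tilt.
#' A guard margin widens the excluded regions so that far Gaussian tails
#' do not bias the fit. Idempotent on already-corrected scans.
#'
#' @param scan A [strip_signal].
#' @param windows List with `c_window` and `t_window`, as returned by
#'   [locate_bands()].
#' @param guard Extra margin (mm) excluded on each side of both windows
#'   when fitting the baseline.
#' @return Baseline-corrected [strip_signal].
#' @export
baseline_correct <- function(scan, windows, guard = 2) {
  scan <- as_strip_signal(scan)
  check_scalar(guard, "guard")
  if (guard < 0) stop_config("'guard' must be >= 0")
  widen <- function(w) c(w[1] - guard, w[2] + guard)
  off <- !(in_window(scan$positions, widen(windows$c_window)) |
             in_window(scan$positions, widen(windows$t_window)))
  if (sum(off) < 2L)
    stop_config("no off-band samples left to fit a baseline")
  fit <- stats::lm.fit(cbind(1, scan$positions[off]), scan$intensities[off])
  base <- fit$coefficients[1] + fit$coefficients[2] * scan$positions
  with_intensities(scan, scan$intensities - base)
}

#' Reduce a band window to a scalar intensity
#'
#' `"area"` (default) integrates the corrected scan over the window with
#' the trapezoidal rule; `"height"` takes the window maximum. A negative
#' result (possible for near-blank bands under noise) is clipped to zero,
#' since fluorescence is non-negative; clipping the scalar rather than the
#' individual samples avoids rectifying zero-mean noise into a positive
#' bias.
#'
#' @param scan A baseline-corrected [strip_signal].
#' @param window Numeric `c(start, end)` in mm, half-open.
#' @param mode `"area"` or `"height"`.
#' @return Non-negative band intensity.
#' @export
band_value <- function(scan, window, mode = c("area", "height")) {
  scan <- as_strip_signal(scan)
  mode <- match.arg(mode)
  sel <- which(in_window(scan$positions, window))
  if (length(sel) < 1L) stop_domain("empty band window")
  y <- scan$intensities[sel]
  if (mode == "height") return(max(max(y), 0))
  if (length(sel) == 1L) return(0)
  p <- scan$positions[sel]
  max(sum(diff(p) * (y[-1] + y[-length(y)]) / 2), 0)
}

#' Characteristic value (T/C ratio)
#'
#' The assay readout: test-band intensity divided by control-band
#' intensity. A non-positive control value means the strip run failed
#' (no control line) and raises an invalid-strip error.
#'
#' @param t_value Test-band intensity, `>= 0`.
#' @param c_value Control-band intensity, `> 0`.
#' @return `t_value / c_value`.
#' @examples
#' characteristic_value(13392, 20244)  # 0.661529...
#' @export
characteristic_value <- function(t_value, c_value) {
  check_scalar(t_value, "t_value"); check_scalar(c_value, "c_value")
  if (t_value < 0) stop_domain("'t_value' must be >= 0")
  if (c_value <= 0)
    stop_invalid_strip("control band intensity must be positive (missing control line?)")
  t_value / c_value
}

#' Quantify a strip scan end to end
#'
#' Optional wavelet denoising, band localization, baseline correction,
#' band reduction and the T/C ratio, with all intermediates kept for
#' audit.
#'
#' @param scan A [strip_signal].
#' @param layout A [band_layout()].
#' @param config A [denoise_config()] used when `denoise = TRUE`.
#' @param denoise Apply wavelet denoising before quantification?
#' @param mode Band reduction mode, `"area"` or `"height"`.
#' @return An object of class `band_quant`: `t_value`, `c_value`,
#'   `characteristic_value`, plus the located `windows`, the
#'   `threshold_plan` (or `NULL`) and the reduction `mode`.
#' @export
quantify <- function(scan, layout = band_layout(), config = denoise_config(),
                     denoise = TRUE, mode = c("area", "height")) {
  scan <- as_strip_signal(scan)
  mode <- match.arg(mode)
  plan <- NULL
  if (isTRUE(denoise)) {
    out <- denoise(scan, config)
    scan <- out$signal
    plan <- out$plan
  }
  windows <- locate_bands(scan, layout)
  corrected <- baseline_correct(scan, windows)
  t_value <- band_value(corrected, windows$t_window, mode)
  c_value <- band_value(corrected, windows$c_window, mode)
  structure(
    list(t_value = t_value, c_value = c_value,
         characteristic_value = characteristic_value(t_value, c_value),
         windows = windows, plan = plan, mode = mode),
    class = "band_quant"
  )
}

#' @export
print.band_quant <- function(x, ...) {
  cat(sprintf("<band_quant> T=%.6g C=%.6g T/C=%.6g (%s mode)\n",
              x$t_value, x$c_value, x$characteristic_value, x$mode))
  invisible(x)
}
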