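# Calibration curve fitting, inverse prediction, and assay QC statistics
# (replicate precision, blank-based limit of detection).

#' Fit the concentration-characteristic value calibration line
#'
#' Ordinary least squares of characteristic value on concentration.
#' `transform = "linear"` fits on the raw scales (the convention that
#' reproduces the instrument's published linearity, blank included);
#' `"log_log"` fits log10(y) on log10(x) and silently requires strictly
#' positive concentrations and values.
#'
#' @param points `data.frame` with columns `concentration` (ng/ml) and
#'   `characteristic_value`, at least two distinct concentrations.
#' @param transform `"linear"` or `"log_log"`.
#' @return An object of class `calibration_model`: `transform`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @examples
#' pts <- data.frame(concentration = c(0, 1, 2),
#'                   characteristic_value = c(0, 1, 2))
#' fit_calibration(pts)$r_squared  # 1
#' @export
fit_calibration <- function(points, transform = c("linear", "log_log")) {
  transform <- match.arg(transform)
  if (!is.data.frame(points) ||
      !all(c("concentration", "characteristic_value") %in% names(points)))
    stop_domain("'points' needs columns concentration and characteristic_value")
  x <- as.numeric(points$concentration)
  y <- as.numeric(points$characteristic_value)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_domain("calibration points must be finite")
  if (transform == "log_log") {
    if (any(x <= 0) || any(y <= 0))
      stop_domain("log_log transform requires positive concentrations and values")
    x <- log10(x); y <- log10(y)
  }
  if (length(unique(x)) < 2L)
    stop_config("degenerate design: need at least two distinct concentrations")
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(
    list(transform = transform, slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r_squared = min(max(r_squared, 0), 1), n_points = length(x)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: y = %.6g + %.6g x, R^2 = %.4f (n = %d)\n",
              x$transform, x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Invert the calibration to predict concentration
#'
#' @param model A [calibration_model][fit_calibration()] with nonzero slope.
#' @param char_value Characteristic value(s) to invert. Vectorized.
#' @return Predicted concentration(s) in ng/ml. Inversions below zero are
#'   clipped to 0 and flagged in the logical attribute `below_range`.
#' @export
predict_concentration <- function(model, char_value) {
  if (!inherits(model, "calibration_model")) stop_domain("expected a calibration_model")
  if (!is.numeric(char_value) || any(!is.finite(char_value)))
    stop_domain("'char_value' must be finite numeric")
  if (model$slope == 0) stop_config("degenerate model: zero slope")
  if (model$transform == "log_log") {
    if (any(char_value <= 0))
      stop_domain("log_log model requires positive characteristic values")
    conc <- 10^((log10(char_value) - model$intercept) / model$slope)
    below <- rep(FALSE, length(conc))
  } else {
    conc <- (char_value - model$intercept) / model$slope
    below <- conc < 0
    conc[below] <- 0
  }
  structure(conc, below_range = below)
}

#' Replicate precision statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation `CV = sd / mean` of replicate characteristic values.
#'
#' @param values Numeric vector of replicate measurements, length `>= 2`,
#'   with positive mean.
#' @return An object of class `replicate_stats`: `mean`, `sd`, `cv`, `n`.
#' @examples
#' replicate_stats(c(0.661529362, 0.720379174, 0.7140643))
#' @export
replicate_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values)))
    stop_domain("'values' must be a finite numeric vector of length >= 2")
  m <- mean(values)
  if (m <= 0) stop_domain("CV undefined: mean must be positive")
  s <- stats::sd(values)
  structure(list(mean = m, sd = s, cv = s / m, n = length(values)),
            class = "replicate_stats")
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat(sprintf("<replicate_stats> n=%d mean=%.9g sd=%.9g cv=%.9g (%.2f%%)\n",
              x$n, x$mean, x$sd, x$cv, 100 * x$cv))
  invisible(x)
}

#' Blank-based limit-of-detection assessment
#'
#' Formalizes the "close to blank" judgment with the standard rule: a
#' concentration level is detectable when its mean characteristic value
#' exceeds `blank_mean + k * blank_sd` (k = 3 by default, the usual
#' limit-of-blank multiplier).
#'
#' @param blank_values Characteristic values of blank strips, length `>= 1`.
#' @param level_values Named list mapping concentration (as names,
#'   coercible to numeric) to vectors of replicate characteristic values.
#' @param k Non-negative SD multiplier.
#' @return An object of class `lod_report`: `blank_mean`, `blank_sd`,
#'   `decision_threshold`, `level_means`, logical `detectable` per level,
#'   and `lod` (lowest detectable concentration, `NA` if none).
#' @export
lod_assess <- function(blank_values, level_values, k = 3) {
  if (!is.numeric(blank_values) || length(blank_values) < 1L ||
      any(!is.finite(blank_values)))
    stop_domain("'blank_values' must be a nonempty finite numeric vector")
  check_scalar(k, "k")
  if (k < 0) stop_domain("'k' must be >= 0")
  if (!is.list(level_values) || length(level_values) < 1L ||
      is.null(names(level_values)))
    stop_domain("'level_values' must be a named list of replicate vectors")
  concs <- suppressWarnings(as.numeric(names(level_values)))
  if (any(is.na(concs))) stop_domain("level names must be numeric concentrations")
  blank_mean <- mean(blank_values)
  blank_sd <- if (length(blank_values) > 1L) stats::sd(blank_values) else 0
  threshold <- blank_mean + k * blank_sd
  means <- vapply(level_values, function(v) mean(as.numeric(v)), 1.0)
  detectable <- means > threshold
  ord <- order(concs)
  lod <- if (any(detectable)) min(concs[detectable]) else NA_real_
  structure(
    list(blank_mean = blank_mean, blank_sd = blank_sd,
         decision_threshold = threshold,
         concentrations = concs[ord], level_means = unname(means[ord]),
         detectable = unname(detectable[ord]), lod = lod, k = k),
    class = "lod_report"
  )
}

#' @export
print.lod_report <- function(x, ...) {
  cat(sprintf("<lod_report> blank %.4g +/- %.4g, threshold %.4g (k=%g)\n",
              x$blank_mean, x$blank_sd, x$decision_threshold, x$k))
  print(data.frame(concentration = x$concentrations, mean = x$level_means,
                   detectable = x$detectable), row.names = FALSE)
  cat(if (is.na(x$lod)) "no level detectable\n"
      else sprintf("lowest detectable level: %g ng/ml\n", x$lod))
  invisible(x)
}
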