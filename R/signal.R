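#' Construct a 1-D strip scan signal
#'
#' A `strip_signal` is a sampled line scan of a lateral-flow strip: a vector
#' of fluorescence intensities and the positions (in mm) at which they were
#' read. Positions may be omitted, in which case the sample index is used.
#'
#' @param intensities Numeric vector of finite intensities (arbitrary
#'   fluorescence units).
#' @param positions Optional numeric vector of strictly increasing positions
#'   (mm), same length as `intensities`. Defaults to `seq_along(intensities)`.
#' @return An object of class `strip_signal` with elements `positions`,
#'   `intensities` and `n`.
#' @examples
#' s <- strip_signal(sin(seq(0, 2 * pi, length.out = 128)))
#' s$n
#' @export
strip_signal <- function(intensities, positions = NULL) {
  if (!is.numeric(intensities) || length(intensities) < 1L)
    stop_domain("'intensities' must be a nonempty numeric vector")
  if (!all(is.finite(intensities)))
    stop_domain("'intensities' must be finite")
  intensities <- as.numeric(intensities)
  implicit <- is.null(positions)
  if (implicit) positions <- as.numeric(seq_along(intensities))
  if (length(positions) != length(intensities))
    stop_domain("'positions' and 'intensities' must have equal length")
  if (!all(is.finite(positions)) || any(diff(positions) <= 0))
    stop_domain("'positions' must be finite and strictly increasing")
  structure(
    list(positions = as.numeric(positions), intensities = intensities,
         n = length(intensities), implicit_positions = implicit),
    class = "strip_signal"
  )
}

#' @export
print.strip_signal <- function(x, ...) {
  cat(sprintf("<strip_signal> %d samples, positions %.4g..%.4g, intensity %.4g..%.4g\n",
              x$n, x$positions[1L], x$positions[x$n],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
as.data.frame.strip_signal <- function(x, ...) {
  data.frame(position = x$positions, intensity = x$intensities)
}

#' @export
length.strip_signal <- function(x) x$n

# Accept either a strip_signal or a bare numeric vector.
as_strip_signal <- function(x) {
  if (inherits(x, "strip_signal")) return(x)
  if (is.numeric(x)) return(strip_signal(x))
  stop_domain("expected a strip_signal or numeric vector")
}

# Replace intensities, keeping positions.
with_intensities <- function(signal, values) {
  strip_signal(values, positions = if (signal$implicit_positions) NULL else signal$positions)
}
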