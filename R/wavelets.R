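# Pyramid discrete wavelet transform for 1-D signals.
#
# Orthogonal families only; filter taps are the published scaling
# coefficients. Two boundary modes:
#   "symmetric"  - half-sample reflection padding; band lengths follow
#                  floor((n + F - 1)/2); exact reconstruction for any n >= F.
#   "periodic"   - circular (periodized) transform; orthogonal, so signal
#                  energy equals coefficient energy; requires n divisible
#                  by 2^levels.

.scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306, 0.5853546836542067,
          0.6756307362972898, 0.31287159091429995, 0.05441584224310401),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605, -0.1432942383508097,
           -0.061273359067658524, 0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
           0.049137179673607506, 0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609)
)

#' Orthogonal wavelet filter bank
#'
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`, `"db8"`, `"sym4"`,
#'   `"sym8"`. The default family used elsewhere in the package is `"sym4"`,
#'   an orthogonal wavelet with 4 vanishing moments.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` filter taps and
#'   the filter `length`.
#' @export
wavelet_filters <- function(wavelet = "sym4") {
  lo <- .scaling_filters[[wavelet]]
  if (is.null(lo))
    stop_config(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                        paste(names(.scaling_filters), collapse = ", ")))
  hi <- rev(lo) * (-1)^seq_along(lo)  # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = length(lo))
}

#' Maximum useful decomposition depth
#'
#' @param n Signal length.
#' @return `floor(log2(n))`, the depth bound used to validate configurations.
#' @export
max_dwt_levels <- function(n) {
  check_scalar(n, "n")
  if (n < 1) stop_domain("'n' must be >= 1")
  floor(log2(n))
}

conv_full <- function(x, f) {
  out <- numeric(length(x) + length(f) - 1L)
  for (i in seq_along(f)) {
    idx <- i:(i + length(x) - 1L)
    out[idx] <- out[idx] + f[i] * x
  }
  out
}

sym_extend <- function(x, k) {
  n <- length(x)
  c(x[pmin(k:1, n)], x, x[pmax(n - (1:k) + 1L, 1L)])
}

dwt_step_sym <- function(x, filt) {
  k <- filt$length - 1L
  pad <- sym_extend(x, k)
  n_out <- (length(x) + k) %/% 2L
  idx <- seq(filt$length + 1L, by = 2L, length.out = n_out)
  list(approx = conv_full(pad, filt$dec_lo)[idx],
       detail = conv_full(pad, filt$dec_hi)[idx])
}

idwt_step_sym <- function(approx, detail, n_out, filt) {
  upsample <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, by = 2L, length.out = length(cf))] <- cf
    u
  }
  y <- conv_full(upsample(approx), filt$rec_lo) +
    conv_full(upsample(detail), filt$rec_hi)
  skip <- filt$length - 2L
  y[(skip + 1L):(skip + n_out)]
}

dwt_step_per <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(filt$length)) {
    idx <- (base + m - 1L) %% n + 1L
    a <- a + filt$dec_lo[m] * x[idx]
    d <- d + filt$dec_hi[m] * x[idx]
  }
  list(approx = a, detail = d)
}

idwt_step_per <- function(approx, detail, n_out, filt) {
  n <- n_out
  y <- numeric(n)
  base <- 2L * (seq_along(approx) - 1L)
  for (m in seq_len(filt$length)) {
    idx <- (base + m - 1L) %% n + 1L
    y[idx] <- y[idx] + filt$dec_lo[m] * approx + filt$dec_hi[m] * detail
  }
  y
}

#' Multi-level discrete wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus one coarse
#' approximation band. Detail bands are indexed with level `j = 1` the
#' finest scale (most coefficients), matching the convention used by the
#' level-dependent threshold rule.
#'
#' @param signal A [strip_signal] or numeric vector.
#' @param wavelet Wavelet family name, see [wavelet_filters()].
#' @param levels Decomposition depth `L >= 1`; must not exceed
#'   `max_dwt_levels(n)`.
#' @param mode Boundary handling, `"symmetric"` (default) or `"periodic"`.
#' @return An object of class `strip_dwt`: `approx` (coarsest approximation
#'   coefficients), `details` (list of length `levels`, finest first),
#'   `wavelet`, `mode`, `levels`, `n` and the per-level input lengths needed
#'   for reconstruction.
#' @seealso [dwt_reconstruct()]
#' @export
dwt_decompose <- function(signal, wavelet = "sym4", levels = 4L,
                          mode = c("symmetric", "periodic")) {
  signal <- as_strip_signal(signal)
  mode <- match.arg(mode)
  filt <- wavelet_filters(wavelet)
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 1L)
    stop_config("'levels' must be a positive integer")
  n <- signal$n
  if (levels > max_dwt_levels(n))
    stop_config(sprintf("signal of length %d supports at most %d levels (requested %d)",
                        n, max_dwt_levels(n), levels))
  if (mode == "periodic" && n %% (2L^levels) != 0L)
    stop_config("periodic mode requires length divisible by 2^levels")
  step <- if (mode == "symmetric") dwt_step_sym else dwt_step_per
  x <- signal$intensities
  details <- vector("list", levels)
  input_lengths <- integer(levels)
  for (lv in seq_len(levels)) {
    input_lengths[lv] <- length(x)
    s <- step(x, filt)
    details[[lv]] <- s$detail
    x <- s$approx
  }
  structure(
    list(wavelet = wavelet, mode = mode, levels = levels,
         approx = x, details = details, input_lengths = input_lengths,
         n = n, positions = signal$positions,
         implicit_positions = signal$implicit_positions),
    class = "strip_dwt"
  )
}

#' @export
print.strip_dwt <- function(x, ...) {
  cat(sprintf("<strip_dwt> %s/%s, %d levels, n=%d; band lengths: approx %d, details %s\n",
              x$wavelet, x$mode, x$levels, x$n, length(x$approx),
              paste(vapply(x$details, length, 1L), collapse = " ")))
  invisible(x)
}

#' Inverse multi-level wavelet transform
#'
#' @param decomp A `strip_dwt` from [dwt_decompose()], possibly with
#'   modified detail coefficients.
#' @return A [strip_signal] of the original length.
#' @export
dwt_reconstruct <- function(decomp) {
  if (!inherits(decomp, "strip_dwt"))
    stop_domain("expected a 'strip_dwt' object")
  filt <- wavelet_filters(decomp$wavelet)
  step <- if (decomp$mode == "symmetric") idwt_step_sym else idwt_step_per
  expected <- vapply(seq_len(decomp$levels), function(lv) {
    n <- decomp$input_lengths[lv]
    if (decomp$mode == "symmetric") (n + filt$length - 1L) %/% 2L else n %/% 2L
  }, 1L)
  actual <- vapply(decomp$details, length, 1L)
  if (length(decomp$details) != decomp$levels || any(actual != expected))
    stop_domain("inconsistent band lengths in decomposition")
  x <- decomp$approx
  for (lv in rev(seq_len(decomp$levels))) {
    x <- step(x, decomp$details[[lv]], decomp$input_lengths[lv], filt)
  }
  strip_signal(x, positions = if (decomp$implicit_positions) NULL else decomp$positions)
}
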