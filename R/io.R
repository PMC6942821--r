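# File formats: scan CSVs (position,intensity), calibration CSVs, model
# JSON, and the bundled instrument reference tables.

#' Read a strip scan from CSV
#'
#' Accepts two columns `position,intensity` (header required) or a single
#' `intensity` column, in which case positions are the sample index. Parse
#' failures report the offending line number.
#'
#' @param path Path to a UTF-8 CSV file with dot decimal separators.
#' @return A [strip_signal].
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_parse(sprintf("%s: no data rows", path))
  header <- tolower(trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]]))
  two_col <- length(header) >= 2L
  n <- length(lines) - 1L
  pos <- numeric(n); int <- numeric(n)
  for (i in seq_len(n)) {
    cells <- trimws(strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]])
    vals <- suppressWarnings(as.numeric(cells))
    if (length(vals) < (if (two_col) 2L else 1L) || any(is.na(vals)))
      stop_parse(sprintf("%s: malformed row at line %d: '%s'",
                         path, i + 1L, lines[i + 1L]))
    if (two_col) { pos[i] <- vals[1L]; int[i] <- vals[2L] }
    else int[i] <- vals[1L]
  }
  tryCatch(
    if (two_col) strip_signal(int, positions = pos) else strip_signal(int),
    stripwave_domain_error = function(e)
      stop_parse(sprintf("%s: %s", path, conditionMessage(e)))
  )
}

#' Write a strip scan to CSV
#'
#' Values are written with full double precision (17 significant digits)
#' so a write/read round trip is value-faithful.
#'
#' @param signal A [strip_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(signal, path) {
  signal <- as_strip_signal(signal)
  lines <- c("position,intensity",
             sprintf("%.17g,%.17g", signal$positions, signal$intensities))
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration table from CSV
#'
#' Expects columns `concentration_ng_ml` and `characteristic_value`.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `concentration`,
#'   `characteristic_value`, suitable for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop_parse(sprintf("%s: %s", path, conditionMessage(e))))
  if (!all(c("concentration_ng_ml", "characteristic_value") %in% names(df)))
    stop_parse(sprintf("%s: need columns concentration_ng_ml, characteristic_value", path))
  data.frame(concentration = as.numeric(df$concentration_ng_ml),
             characteristic_value = as.numeric(df$characteristic_value))
}

#' Serialize a calibration model to JSON
#'
#' @param model A [calibration_model][fit_calibration()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "calibration_model")) stop_domain("expected a calibration_model")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `calibration_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("transform", "slope", "intercept", "r_squared", "n_points")
  if (!all(need %in% names(obj)))
    stop_parse(sprintf("%s: not a calibration model", path))
  structure(obj[need], class = "calibration_model")
}

#' Bundled instrument reference tables
#'
#' Validation tables from a europium-chelate fluorescence lateral-flow
#' assay for Cryptococcus capsular polysaccharide, shipped with the
#' package: `linearity` (one dilution series, raw T and C counts with the
#' instrument's characteristic values), `repeatability` (three replicate
#' strips at 1, 10 and 100 ng/ml) and `lod` (mean characteristic values of
#' the detection-limit series, blank included).
#'
#' @return Named list of three `data.frame`s.
#' @examples
#' ref <- reference_tables()
#' fit_calibration(data.frame(
#'   concentration = ref$linearity$concentration_ng_ml,
#'   characteristic_value = ref$linearity$characteristic_value))
#' @export
reference_tables <- function() {
  load <- function(name) {
    path <- system.file("extdata", name, package = "stripwave", mustWork = TRUE)
    utils::read.csv(path)
  }
  list(linearity = load("linearity_reference.csv"),
       repeatability = load("repeatability_reference.csv"),
       lod = load("lod_reference.csv"))
}
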