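# Pipeline configuration, the end-to-end runner, and the command-line
# dispatcher. All randomness flows through explicit seeds in the config so
# reruns with identical config and inputs are byte-identical.

.run_config_keys <- list(
  denoise = c("wavelet", "levels", "threshold_fn", "rule", "sigma_mode",
              "sigma", "mode"),
  layout = c("mode", "c_window", "t_window", "band_width", "min_separation",
             "c_side", "prominence"),
  simulate = c("concentrations", "replicates", "noise_sigma", "response_kind",
               "response_slope", "response_background"),
  top = c("denoise", "layout", "simulate", "quant_mode", "transform",
          "denoise_enabled", "seed")
)

#' Validated pipeline configuration
#'
#' One document holding the denoising, band-layout, quantification and
#' calibration settings plus the master seed. Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param config Named list, e.g. parsed from a JSON file. Recognized keys:
#'   `denoise` (arguments of [denoise_config()]), `layout` (arguments of
#'   [band_layout()]), `simulate` (`concentrations`, `replicates`,
#'   `noise_sigma`, `response_kind`, `response_slope`,
#'   `response_background`), `quant_mode` (`"area"`/`"height"`),
#'   `transform` (`"linear"`/`"log_log"`), `denoise_enabled` (logical),
#'   `seed` (integer).
#' @return An object of class `run_config` with all components built and
#'   validated.
#' @export
run_config <- function(config = list()) {
  if (!is.list(config)) stop_config("'config' must be a list")
  reject_unknown <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop_config(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
  reject_unknown(config, .run_config_keys$top, "config")
  # [[ rather than $: partial matching must not leak e.g. denoise_enabled
  # into the denoise sub-config
  reject_unknown(config[["denoise"]] %||% list(), .run_config_keys$denoise, "denoise")
  reject_unknown(config[["layout"]] %||% list(), .run_config_keys$layout, "layout")
  reject_unknown(config[["simulate"]] %||% list(), .run_config_keys$simulate, "simulate")
  dn <- do.call(denoise_config, config[["denoise"]] %||% list())
  lay_args <- config[["layout"]] %||% list()
  for (w in c("c_window", "t_window"))
    if (!is.null(lay_args[[w]])) lay_args[[w]] <- as.numeric(lay_args[[w]])
  lay <- do.call(band_layout, lay_args)
  sim <- config[["simulate"]] %||% list(concentrations = c(0, 0.05, 0.1, 1, 10, 100),
                                        replicates = 3L, noise_sigma = 300)
  structure(
    list(denoise = dn, layout = lay, simulate = sim,
         quant_mode = match.arg(config[["quant_mode"]] %||% "area", c("area", "height")),
         transform = match.arg(config[["transform"]] %||% "linear", c("linear", "log_log")),
         denoise_enabled = isTRUE(config[["denoise_enabled"]] %||% TRUE),
         seed = as.integer(config[["seed"]] %||% 1L)),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical JSON serialization, for reproducibility audits
# (tools::md5sum wants a file, so serialize to a temp path).
content_digest <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Software analogue of the instrument workflow: obtain scans (simulate a
#' dilution series, or read the given CSV files), denoise, quantify each
#' scan, and fit the calibration line. Returns a machine-readable log with
#' input/config digests and every intermediate result.
#'
#' @param config A [run_config()] (or plain list passed through it).
#' @param inputs Optional `data.frame` with columns `path` (scan CSV) and
#'   `concentration`; when `NULL`, scans are simulated from
#'   `config$simulate`.
#' @return An object of class `run_log`: `config_digest`, `input_digest`,
#'   `timestamp`, `quants` (data.frame of per-scan results), `model`
#'   (calibration fit or `NULL` when fewer than two distinct
#'   concentrations), `plans` (threshold plans).
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.null(inputs)) {
    sim <- config$simulate
    model <- response_model(kind = sim$response_kind %||% "linear",
                            slope = sim$response_slope %||% 0.0065,
                            background = sim$response_background %||% 0.01)
    series <- simulate_dilution_series(
      concentrations = as.numeric(sim$concentrations),
      model = model,
      replicates = as.integer(sim$replicates %||% 3L),
      noise_sigma = as.numeric(sim$noise_sigma %||% 300),
      seed = config$seed)
    scans <- lapply(series, `[[`, "signal")
    concs <- vapply(series, function(s) s$truth$concentration, 1.0)
    input_digest <- content_digest(list(simulated = TRUE, simulate = sim,
                                        seed = config$seed))
  } else {
    if (!is.data.frame(inputs) || !all(c("path", "concentration") %in% names(inputs)))
      stop_config("'inputs' needs columns path and concentration")
    scans <- lapply(inputs$path, read_scan_csv)
    concs <- as.numeric(inputs$concentration)
    input_digest <- content_digest(lapply(scans, function(s) s$intensities))
  }
  quants <- lapply(scans, function(s)
    quantify(s, layout = config$layout, config = config$denoise,
             denoise = config$denoise_enabled, mode = config$quant_mode))
  quant_df <- data.frame(
    concentration = concs,
    t_value = vapply(quants, `[[`, 1.0, "t_value"),
    c_value = vapply(quants, `[[`, 1.0, "c_value"),
    characteristic_value = vapply(quants, `[[`, 1.0, "characteristic_value"))
  model_fit <- if (length(unique(concs)) >= 2L) {
    fit_calibration(data.frame(concentration = quant_df$concentration,
                               characteristic_value = quant_df$characteristic_value),
                    transform = config$transform)
  }
  structure(
    list(config_digest = content_digest(unclass(config)),
         input_digest = input_digest,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         quants = quant_df, model = model_fit,
         plans = lapply(quants, `[[`, "plan")),
    class = "run_log"
  )
}

#' @export
print.run_log <- function(x, ...) {
  cat(sprintf("<run_log> %d scans, config %s..., input %s...\n",
              nrow(x$quants), substr(x$config_digest, 1, 8),
              substr(x$input_digest, 1, 8)))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

# ---- command-line interface -------------------------------------------

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop_config(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE  # bare switch, e.g. --no-denoise
      i <- i + 1L
    }
  }
  out
}

flag_num <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop_config(sprintf("--%s must be numeric", key))
  x
}

cli_denoise_config <- function(flags) {
  denoise_config(
    wavelet = flags[["wavelet"]] %||% "sym4",
    levels = flag_num(flags, "levels", 4),
    threshold_fn = flags[["fn"]] %||% "improved",
    rule = switch(flags[["rule"]] %||% "level",
                  level = , level_dependent = "level_dependent",
                  universal = "universal",
                  stop_config("--rule must be universal or level")),
    sigma_mode = if (is.null(flags[["sigma"]])) "estimate_from_finest" else "fixed",
    sigma = flag_num(flags, "sigma"))
}

cli_simulate <- function(flags) {
  out_dir <- flags[["out-dir"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  concs <- as.numeric(strsplit(flags[["concs"]] %||% "0,0.05,0.1,1,10,100", ",")[[1L]])
  series <- simulate_dilution_series(
    concentrations = concs,
    replicates = as.integer(flag_num(flags, "replicates", 3)),
    noise_sigma = flag_num(flags, "noise-sigma", 300),
    seed = as.integer(flag_num(flags, "seed", 1)))
  manifest <- lapply(seq_along(series), function(i) {
    file <- sprintf("scan_%03d.csv", i)
    write_scan_csv(series[[i]]$signal, file.path(out_dir, file))
    c(list(file = file), unclass(series[[i]]$truth))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("wrote %d scans + truth.json to %s", length(series), out_dir))
}

cli_denoise_cmd <- function(flags) {
  if (is.null(flags[["in"]]) || is.null(flags[["out"]]))
    stop_config("denoise requires --in and --out")
  out <- denoise(read_scan_csv(flags[["in"]]), cli_denoise_config(flags))
  write_scan_csv(out$signal, flags[["out"]])
  jsonlite::write_json(unclass(out$plan), paste0(flags[["out"]], ".plan.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("wrote %s (+ .plan.json)", flags[["out"]]))
}

cli_quantify <- function(flags) {
  if (is.null(flags[["in"]])) stop_config("quantify requires --in")
  layout <- if (!is.null(flags[["layout"]])) {
    lj <- jsonlite::read_json(flags[["layout"]], simplifyVector = TRUE)
    do.call(band_layout, lj)
  } else band_layout()
  q <- quantify(read_scan_csv(flags[["in"]]), layout = layout,
                config = cli_denoise_config(flags),
                denoise = !isTRUE(flags[["no-denoise"]]),
                mode = flags[["mode"]] %||% "area")
  payload <- list(t_value = q$t_value, c_value = q$c_value,
                  characteristic_value = q$characteristic_value,
                  mode = q$mode, windows = q$windows,
                  threshold_plan = if (!is.null(q$plan)) unclass(q$plan))
  if (!is.null(flags[["out"]]))
    jsonlite::write_json(payload, flags[["out"]], auto_unbox = TRUE, digits = NA)
  else cat(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), "\n")
}

cli_calibrate <- function(flags) {
  if (is.null(flags[["in"]]) || is.null(flags[["out"]]))
    stop_config("calibrate requires --in and --out")
  model <- fit_calibration(read_calibration_csv(flags[["in"]]),
                           transform = flags[["transform"]] %||% "linear")
  write_model_json(model, flags[["out"]])
  message(sprintf("R^2 = %.4f", model$r_squared))
}

cli_predict <- function(flags) {
  if (is.null(flags[["model"]]) || is.null(flags[["char-value"]]))
    stop_config("predict requires --model and --char-value")
  model <- read_model_json(flags[["model"]])
  conc <- predict_concentration(model, flag_num(flags, "char-value"))
  cat(jsonlite::toJSON(list(concentration_ng_ml = as.numeric(conc),
                            below_range = attr(conc, "below_range")),
                       auto_unbox = TRUE, digits = NA), "\n")
}

cli_qc <- function(flags) {
  if (is.null(flags[["replicates"]])) stop_config("qc requires --replicates")
  df <- utils::read.csv(flags[["replicates"]])
  if (!"characteristic_value" %in% names(df))
    stop_parse("replicates CSV needs a characteristic_value column")
  st <- replicate_stats(as.numeric(df$characteristic_value))
  cat(jsonlite::toJSON(unclass(st), auto_unbox = TRUE, digits = NA), "\n")
}

cli_lod <- function(flags) {
  if (is.null(flags[["blanks"]]) || is.null(flags[["levels"]]))
    stop_config("lod requires --blanks and --levels")
  blanks <- utils::read.csv(flags[["blanks"]])
  levels <- utils::read.csv(flags[["levels"]])
  if (!"characteristic_value" %in% names(blanks) ||
      !all(c("concentration_ng_ml", "characteristic_value") %in% names(levels)))
    stop_parse("blanks needs characteristic_value; levels needs concentration_ng_ml + characteristic_value")
  lv <- split(as.numeric(levels$characteristic_value), levels$concentration_ng_ml)
  rep_ <- lod_assess(as.numeric(blanks$characteristic_value), lv,
                     k = flag_num(flags, "k", 3))
  cat(jsonlite::toJSON(unclass(rep_), auto_unbox = TRUE, digits = NA), "\n")
}

cli_bench <- function(flags) {
  clean <- test_signal(flags[["signal"]] %||% "heavisine",
                       n = flag_num(flags, "n", 1024))
  tab <- benchmark_denoisers(clean,
                             noise_sigma = flag_num(flags, "sigma", 1),
                             n_reps = as.integer(flag_num(flags, "reps", 20)),
                             seed = as.integer(flag_num(flags, "seed", 1)))
  if (!is.null(flags[["out"]])) utils::write.csv(tab, flags[["out"]], row.names = FALSE)
  else utils::write.csv(tab, stdout(), row.names = FALSE)
}

cli_run <- function(flags) {
  cfg <- if (!is.null(flags[["config"]]))
    run_config(jsonlite::read_json(flags[["config"]], simplifyVector = TRUE))
  else run_config()
  if (!is.null(flags[["seed"]])) cfg$seed <- as.integer(flag_num(flags, "seed"))
  log <- run_pipeline(cfg)
  out_dir <- flags[["out-dir"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(log$model)) write_model_json(log$model, file.path(out_dir, "model.json"))
  payload <- list(config_digest = log$config_digest,
                  input_digest = log$input_digest,
                  quants = log$quants,
                  model = if (!is.null(log$model)) unclass(log$model))
  jsonlite::write_json(payload, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("wrote run_log.json%s to %s",
                  if (!is.null(log$model)) " + model.json" else "", out_dir))
}

#' Command-line dispatcher
#'
#' Entry point for `Rscript -e 'stripwave::stripwave_cli()'` style use.
#' Subcommands: `simulate`, `denoise`, `quantify`, `calibrate`, `predict`,
#' `qc`, `lod`, `bench`, `run`. Each failure is mapped to a stable exit
#' code, see [exit_codes()].
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Integer exit code, invisibly (0 on success). Call
#'   `quit(status = stripwave_cli())` from a script to propagate it.
#' @export
stripwave_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L) stop_config("usage: <subcommand> [--flags]")
    cmd <- args[[1L]]
    flags <- parse_flags(args[-1L])
    switch(cmd,
           simulate = cli_simulate(flags),
           denoise = cli_denoise_cmd(flags),
           quantify = cli_quantify(flags),
           calibrate = cli_calibrate(flags),
           predict = cli_predict(flags),
           qc = cli_qc(flags),
           lod = cli_lod(flags),
           bench = cli_bench(flags),
           run = cli_run(flags),
           stop_config(sprintf("unknown subcommand '%s'", cmd)))
    0L
  }, stripwave_error = function(e) {
    message("error: ", conditionMessage(e))
    as.integer(exit_code_for(e))
  })
  invisible(status)
}
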