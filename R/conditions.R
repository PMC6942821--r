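# Structured conditions: every user-facing failure carries a class the CLI
# maps to a stable exit code (see exit_codes()).

stop_domain <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("stripwave_domain_error", "stripwave_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("stripwave_config_error", "stripwave_error")))
}

stop_invalid_strip <- function(msg) {
  stop(errorCondition(msg, class = c("stripwave_invalid_strip", "stripwave_error")))
}

stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("stripwave_parse_error", "stripwave_error")))
}

#' Stable exit codes for the command-line interface
#'
#' @return Named integer vector: `success` (0), `error` (1, any other
#'   failure), `config` (2, invalid configuration), `invalid_strip` (3,
#'   quantification rejected the strip, e.g. missing control line),
#'   `parse` (4, malformed input file).
#' @export
exit_codes <- function() {
  c(success = 0L, error = 1L, config = 2L, invalid_strip = 3L, parse = 4L)
}

exit_code_for <- function(cond) {
  codes <- exit_codes()
  if (inherits(cond, "stripwave_config_error")) return(codes[["config"]])
  if (inherits(cond, "stripwave_invalid_strip")) return(codes[["invalid_strip"]])
  if (inherits(cond, "stripwave_parse_error")) return(codes[["parse"]])
  codes[["error"]]
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
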