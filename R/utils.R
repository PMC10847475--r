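# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setDT setorder fread fwrite rbindlist uniqueN :=
#' @importFrom stats dhyper phyper pcauchy qchisq median rbinom rpois rnbinom runif setNames
#' @importFrom methods as
NULL

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("urv_format_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = c("urv_config_error", "error")))
}

check_columns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop_format("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(dt)
}
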