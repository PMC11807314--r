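# Internal error helpers: configuration errors (bad user input / settings)
# and data errors (problems in the data files themselves). The CLI maps
# these to exit codes 1 and 2 respectively.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("timerflow_config_error", "timerflow_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("timerflow_data_error", "timerflow_error")))
}

# Minimum number of gated negative-control cells required for the
# normalization statistics (max and MAD/SD) to be meaningful.
MIN_GATE_SIZE <- 10L

QUADRANT_LEVELS <- c("NegNeg", "BluePosRedNeg", "BluePosRedPos", "BlueNegRedPos")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @keywords internal
msg_log <- function(..., verbose = getOption("timerflow.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# All CSV output goes through this writer so that the dialect (comma,
# header, "." decimal) and the 6-significant-digit float convention are
# applied uniformly, and reruns are byte-identical.
write_output_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
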