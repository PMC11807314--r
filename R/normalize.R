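#' Floored log10 transform of raw fluorescence
#'
#' Maps each raw value v to `log10(max(v, log_floor))`. The floor (default
#' 1 raw unit) makes the transform total in the presence of zero or
#' negative raw values, which arise routinely from baseline-subtracted
#' cytometer exports. Decades (log10) are the flow-cytometry convention.
#'
#' @param values raw fluorescence vector.
#' @param log_floor positive raw-unit floor applied before the log.
#' @return Log10-units vector of the same length.
#' @export
log_transform <- function(values, log_floor = 1) {
  if (!is_scalar_number(log_floor) || log_floor <= 0) {
    stop_config("log_floor must be a positive number")
  }
  n_floored <- sum(values < log_floor, na.rm = TRUE)
  if (n_floored > 0) msg_log(sprintf("floored %d value(s) at %g", n_floored, log_floor))
  log10(pmax(values, log_floor))
}

#' Normalization statistics from the gated negative control
#'
#' For each Timer channel of the gated negative control, computes the
#' location (maximum of the log10-transformed fluorescence) and the scale
#' (sample SD with n-1 denominator, or the median absolute deviation
#' scaled by 1.4826 so that it estimates the SD under normality). MAD is
#' the default because it is robust to the outliers that survive gating.
#'
#' @param gated_neg gated negative-control [cell_matrix()].
#' @param blue_channel,red_channel channel names.
#' @param method `"MAD"` (default) or `"SD"`.
#' @param log_floor raw-unit floor for [log_transform()].
#' @param min_gate minimum gate size.
#' @return A `normalization_params` list: `method`, `log_base` (10),
#'   `log_floor`, `blue_location`, `blue_scale`, `red_location`,
#'   `red_scale`, `n_gated_neg`.
#' @export
compute_normalization_params <- function(gated_neg, blue_channel, red_channel,
                                         method = c("MAD", "SD"),
                                         log_floor = 1,
                                         min_gate = MIN_GATE_SIZE) {
  method <- match.arg(method)
  if (nrow(gated_neg) < min_gate) {
    stop_data("gated negative control has ", nrow(gated_neg),
              " cells; at least ", min_gate, " required")
  }
  one_channel <- function(channel) {
    lv <- log_transform(gated_neg[[channel]], log_floor)
    if (length(unique(lv)) < 2L) {
      stop_data("degenerate negative control: all log values identical in '",
                channel, "'")
    }
    scale <- if (method == "SD") stats::sd(lv) else stats::mad(lv)
    if (!is_scalar_number(scale) || scale <= 0) {
      stop_data("degenerate negative control: zero ", method,
                " in channel '", channel, "'")
    }
    list(location = max(lv), scale = scale)
  }
  b <- one_channel(blue_channel)
  r <- one_channel(red_channel)
  structure(list(method = method, log_base = 10, log_floor = log_floor,
                 blue_location = b$location, blue_scale = b$scale,
                 red_location = r$location, red_scale = r$scale,
                 n_gated_neg = nrow(gated_neg)),
            class = "normalization_params")
}

#' @export
print.normalization_params <- function(x, ...) {
  cat(sprintf(paste0("<normalization_params> method=%s, log10 floor=%g, ",
                     "n_gated_neg=%d\n  blue: location=%.4f scale=%.4f\n",
                     "  red:  location=%.4f scale=%.4f\n"),
              x$method, x$log_floor, x$n_gated_neg,
              x$blue_location, x$blue_scale, x$red_location, x$red_scale))
  invisible(x)
}

#' Normalize log fluorescence against the negative control
#'
#' Elementwise `(x - location) / scale`, where the location is the
#' maximum and the scale the SD (or scaled MAD) of the log-transformed
#' gated negative control. Values are NOT clamped here; negative
#' normalized values (below autofluorescence ceiling) are clamped only
#' inside the trigonometric transform.
#'
#' @param log_values log10-units vector.
#' @param location,scale log10-units statistics; `scale > 0`.
#' @return Dimensionless vector.
#' @export
normalize_channel <- function(log_values, location, scale) {
  if (!is_scalar_number(scale) || scale <= 0) stop_config("scale must be > 0")
  (log_values - location) / scale
}
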