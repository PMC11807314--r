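#' Specify how Timer gating thresholds are obtained
#'
#' Thresholds for Timer Blue and Red fluorescence are either computed as
#' per-channel empirical quantiles of the negative control (automatic
#' mode) or supplied directly in raw fluorescence units (manual mode,
#' replacing interactive gating).
#'
#' @param method `"quantile"` or `"manual"`.
#' @param quantile_q quantile in (0, 1) used when `method = "quantile"`.
#'   The default 0.975 treats the upper 2.5% autofluorescence tail of the
#'   negative control as the positivity boundary.
#' @param manual_blue,manual_red raw-unit thresholds, both required when
#'   `method = "manual"`.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(method = c("quantile", "manual"),
                           quantile_q = 0.975,
                           manual_blue = NULL, manual_red = NULL) {
  method <- match.arg(method)
  if (method == "quantile") {
    if (!is_scalar_number(quantile_q) || quantile_q <= 0 || quantile_q >= 1) {
      stop_config("quantile_q must lie strictly in (0, 1), got ", quantile_q)
    }
  } else {
    if (is.null(manual_blue) || is.null(manual_red)) {
      stop_config("manual thresholding requires both manual_blue and manual_red")
    }
    if (!is_scalar_number(manual_blue) || !is_scalar_number(manual_red)) {
      stop_config("manual thresholds must be finite numbers")
    }
  }
  structure(list(method = method, quantile_q = quantile_q,
                 manual_blue = manual_blue, manual_red = manual_red),
            class = "threshold_spec")
}

#' Compute gating thresholds from the negative control
#'
#' In quantile mode the threshold for each Timer channel is the empirical
#' quantile (linear interpolation between order statistics, R type 7) of
#' the negative control's raw fluorescence at `quantile_q`; in manual
#' mode the supplied values are used verbatim. The blue threshold plays
#' the role of the y-axis gate and the red threshold the x-axis gate in
#' the conventional blue-vs-red 2D plot.
#'
#' @param neg negative-control [cell_matrix()].
#' @param spec a [threshold_spec()].
#' @param blue_channel,red_channel channel names.
#' @param min_gate minimum negative-control size required.
#' @return A `gate_thresholds` list with elements `blue` and `red`.
#' @export
compute_gate_thresholds <- function(neg, spec, blue_channel, red_channel,
                                    min_gate = MIN_GATE_SIZE) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$method == "manual") {
    thr <- list(blue = spec$manual_blue, red = spec$manual_red)
  } else {
    if (nrow(neg) < min_gate) {
      stop_data("negative control has only ", nrow(neg),
                " cells; at least ", min_gate, " required")
    }
    thr <- list(
      blue = unname(stats::quantile(neg[[blue_channel]], spec$quantile_q,
                                    type = 7, names = FALSE)),
      red = unname(stats::quantile(neg[[red_channel]], spec$quantile_q,
                                   type = 7, names = FALSE)))
  }
  if (!is_scalar_number(thr$blue) || !is_scalar_number(thr$red)) {
    stop_data("thresholds must be finite")
  }
  structure(thr, class = "gate_thresholds")
}

#' Gate the negative control below both thresholds
#'
#' Retains negative-control cells with blue <= blue threshold AND red <=
#' red threshold (inclusive: a cell exactly at threshold is background).
#' Row order is preserved. The gated subset supplies the normalization
#' statistics, so a gate smaller than `min_gate` is fatal.
#'
#' @inheritParams compute_gate_thresholds
#' @param thr a `gate_thresholds`.
#' @return The gated [cell_matrix()].
#' @export
gate_negative_cells <- function(neg, thr, blue_channel, red_channel,
                                min_gate = MIN_GATE_SIZE) {
  keep <- neg[[blue_channel]] <= thr$blue & neg[[red_channel]] <= thr$red
  gated <- cell_matrix(neg[keep, , drop = FALSE], sample_id_of(neg))
  if (nrow(gated) < min_gate) {
    stop_data("gated negative control too small: ", nrow(gated), " of ",
              nrow(neg), " cells retained (minimum ", min_gate, ")")
  }
  msg_log(sprintf("gated negative control: %d of %d cells retained",
                  nrow(gated), nrow(neg)))
  gated
}

#' Classify Timer positivity
#'
#' A cell is Timer-positive when its raw blue OR raw red fluorescence
#' strictly exceeds the respective threshold; cells at or below both
#' thresholds are autofluorescent background and are excluded from
#' angle/intensity analysis.
#'
#' @param blue_raw,red_raw raw fluorescence vectors.
#' @param thr a `gate_thresholds`.
#' @return Logical vector.
#' @export
classify_timer_positive <- function(blue_raw, red_raw, thr) {
  blue_raw > thr$blue | red_raw > thr$red
}

#' Assign quadrant gates
#'
#' Partitions cells by the blue/red thresholds into the four conventional
#' quadrants: `NegNeg` (both at/below), `BluePosRedNeg`, `BlueNegRedPos`,
#' `BluePosRedPos`. Every cell receives exactly one label.
#'
#' @inheritParams classify_timer_positive
#' @return Factor with levels `NegNeg`, `BluePosRedNeg`, `BluePosRedPos`,
#'   `BlueNegRedPos`.
#' @export
quadrant_classify <- function(blue_raw, red_raw, thr) {
  bp <- blue_raw > thr$blue
  rp <- red_raw > thr$red
  lab <- ifelse(bp & rp, "BluePosRedPos",
         ifelse(bp, "BluePosRedNeg",
         ifelse(rp, "BlueNegRedPos", "NegNeg")))
  factor(lab, levels = QUADRANT_LEVELS)
}
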