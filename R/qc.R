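#' Per-sample summary statistics
#'
#' Summarizes one transformed sample together with its raw counterpart:
#' quadrant fractions over all cells, mean fluorescence intensities
#' (arithmetic mean of raw values by default, geometric mean optionally),
#' mean FSC when a scatter channel is present, and mean Timer Angle /
#' Intensity over Timer-positive cells only (missing when no cell is
#' positive).
#'
#' @param transformed a `transformed_cells` data frame.
#' @param raw the matching [cell_matrix()] (row-aligned with
#'   `transformed`).
#' @param blue_channel,red_channel Timer channel names in `raw`.
#' @param fsc_channel scatter channel name, or `NULL`/absent to skip.
#' @param group group label carried into the summary.
#' @param mfi `"arithmetic"` (default) or `"geometric"` mean for the MFI
#'   columns.
#' @return One-row data frame (`sample_summary`).
#' @export
summarize_sample <- function(transformed, raw, blue_channel, red_channel,
                             fsc_channel = "FSC", group = NA_character_,
                             mfi = c("arithmetic", "geometric")) {
  mfi <- match.arg(mfi)
  if (nrow(transformed) != nrow(raw)) {
    stop_data("transformed and raw tables are misaligned (",
              nrow(transformed), " vs ", nrow(raw), " rows)")
  }
  avg <- function(x) if (mfi == "arithmetic") mean(x) else exp(mean(log(pmax(x, .Machine$double.eps))))
  n <- nrow(transformed)
  qf <- as.numeric(table(transformed$quadrant)) / n
  pos <- transformed$timer_positive
  data.frame(
    sample_id = attr(transformed, "sample_id"),
    group = group,
    n_total = n,
    n_timer_positive = sum(pos),
    frac_NegNeg = qf[1], frac_BluePosRedNeg = qf[2],
    frac_BluePosRedPos = qf[3], frac_BlueNegRedPos = qf[4],
    mfi_blue = avg(raw[[blue_channel]]),
    mfi_red = avg(raw[[red_channel]]),
    mean_fsc = if (!is.null(fsc_channel) && fsc_channel %in% names(raw))
      avg(raw[[fsc_channel]]) else NA_real_,
    mean_angle = if (any(pos)) mean(transformed$angle[pos], na.rm = TRUE) else NA_real_,
    mean_intensity = if (any(pos)) mean(transformed$intensity[pos], na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Summaries for every sample of a batch result
#'
#' Re-reads each raw file listed in the result's sample definition and
#' applies [summarize_sample()]; one row per file, control included.
#'
#' @param result a `tocky_result`.
#' @param manifest the `sample_manifest` the result was computed from.
#' @param ... passed to [summarize_sample()].
#' @return Data frame of per-sample summaries.
#' @export
summarize_batch <- function(result, manifest, ...) {
  entries <- result$sample_definition
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    entry <- entries[i, ]
    raw <- read_cell_matrix(entry, manifest$common_variables,
                            required = c(result$blue_channel, result$red_channel))
    summarize_sample(result$samples[[entry$sample_id]], raw,
                     result$blue_channel, result$red_channel,
                     group = entry$group, ...)
  })
  do.call(rbind, rows)
}

#' Remove a sample group from a batch result
#'
#' Drops every sample belonging to the given group label from the
#' result's samples, counts and sample definition (e.g. a zero-hour
#' timepoint contaminated by cells that accumulated mature Timer before
#' the experiment). The exclusion is logged.
#'
#' @param result a `tocky_result`.
#' @param group label to exclude.
#' @return The filtered `tocky_result`.
#' @export
exclude_group <- function(result, group) {
  available <- unique(result$sample_definition$group)
  if (!(group %in% available)) {
    stop_config("unknown group '", group, "'; available: ",
                paste(available, collapse = ", "))
  }
  drop_ids <- result$sample_definition$sample_id[
    result$sample_definition$group == group]
  result$samples <- result$samples[setdiff(names(result$samples), drop_ids)]
  result$counts <- result$counts[result$counts$group != group, , drop = FALSE]
  result$sample_definition <- result$sample_definition[
    result$sample_definition$group != group, , drop = FALSE]
  msg_log(sprintf("excluded group '%s' (%d sample(s))", group, length(drop_ids)))
  result
}

collect_plot_data <- function(result, mode) {
  entries <- result$sample_definition
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    sid <- entries$sample_id[i]
    tc <- result$samples[[sid]]
    base <- data.frame(sample_id = sid, group = entries$group[i],
                       stringsAsFactors = FALSE)
    if (mode == "timer_fluorescence") {
      cbind(base[rep(1, nrow(tc)), ], x = tc$blue_log, y = tc$red_log)
    } else if (mode == "normalized_timer_fluorescence") {
      keep <- tc$timer_positive
      cbind(base[rep(1, sum(keep)), ], x = tc$blue_norm[keep], y = tc$red_norm[keep])
    } else {
      keep <- tc$timer_positive & !is.na(tc$angle)
      cbind(base[rep(1, sum(keep)), ], x = tc$angle[keep], y = tc$intensity[keep])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-wise 2D diagnostic plots of a batch result
#'
#' Three plot modes mirror the preprocessing stages:
#' `"timer_fluorescence"` shows raw log10 blue vs red with the quadrant
#' threshold lines; `"normalized_timer_fluorescence"` shows normalized
#' blue vs red for Timer-positive cells; `"angle_intensity"` shows Timer
#' Angle (x, fixed 0-90 degrees) vs Timer Intensity. One panel per
#' group. The plotted points are always returned — and optionally
#' written — as a plain CSV (`sample_id, group, x, y`), a pure
#' projection of the result, so checks operate on data rather than
#' rendered pixels.
#'
#' @param result a `tocky_result`.
#' @param mode one of `"timer_fluorescence"`,
#'   `"normalized_timer_fluorescence"`, `"angle_intensity"`.
#' @param group_order optional character vector fixing panel order.
#' @param output_dir if non-NULL, writes `plotdata_<mode>.csv` and
#'   `plot_<mode>.png` there.
#' @return List with `data` (the plot-data frame) and `plot` (a ggplot).
#' @export
plot_tocky <- function(result,
                       mode = c("timer_fluorescence",
                                "normalized_timer_fluorescence",
                                "angle_intensity"),
                       group_order = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  df <- collect_plot_data(result, mode)
  if (is.null(group_order)) group_order <- unique(df$group)
  df$group <- factor(df$group, levels = group_order)
  df <- df[!is.na(df$group), , drop = FALSE]
  labs <- switch(mode,
    timer_fluorescence = c("log10 Timer Blue", "log10 Timer Red"),
    normalized_timer_fluorescence = c("Normalized Timer Blue", "Normalized Timer Red"),
    angle_intensity = c("Timer Angle (deg)", "Timer Intensity"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_bw()
  if (mode == "timer_fluorescence") {
    lf <- result$params$log_floor
    p <- p +
      ggplot2::geom_vline(xintercept = log10(max(result$thresholds$blue, lf)),
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = log10(max(result$thresholds$red, lf)),
                          linetype = "dashed")
  }
  if (mode == "angle_intensity") {
    p <- p + ggplot2::xlim(0, 90)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(output_dir, paste0("plotdata_", mode, ".csv")),
                     row.names = FALSE, quote = FALSE)
    ggplot2::ggsave(file.path(output_dir, paste0("plot_", mode, ".png")),
                    p, width = 9, height = 7, dpi = 120)
  }
  list(data = df, plot = p)
}
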