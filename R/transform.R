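#' Trigonometric transformation into Timer Angle and Intensity
#'
#' Converts normalized blue/red coordinates to polar form. Normalized
#' values are first clamped at 0 (expression at or below the
#' autofluorescence ceiling contributes nothing), then
#' \deqn{I = \sqrt{B^2 + R^2}, \qquad
#'       \theta = \arccos(B / I) \cdot 180 / \pi,}
#' so the angle runs from 0 degrees (pure blue, new expression) to 90
#' degrees (pure red, aged expression). Cells at the origin (I = 0) have
#' no defined direction and carry a missing angle.
#'
#' @param blue_norm,red_norm dimensionless normalized fluorescence.
#' @return Data frame with columns `angle` (degrees, `NA` when I = 0) and
#'   `intensity`.
#' @export
trig_transform <- function(blue_norm, red_norm) {
  b <- pmax(blue_norm, 0)
  r <- pmax(red_norm, 0)
  intensity <- sqrt(b^2 + r^2)
  angle <- ifelse(intensity > 0,
                  acos(pmin(pmax(b / intensity, 0), 1)) * 180 / pi,
                  NA_real_)
  data.frame(angle = angle, intensity = intensity)
}

#' Transform one sample with fixed thresholds and parameters
#'
#' Applies the full per-cell pipeline: floored log10 transform of both
#' Timer channels; normalization against the negative-control statistics
#' (or, with `normalize = FALSE`, centering only — the log values minus
#' the location, no scale division); Timer-positivity and quadrant
#' classification from the raw values against the thresholds; and the
#' trigonometric transform, computed for Timer-positive cells only
#' (background cells carry missing angle and intensity).
#'
#' @param sample a [cell_matrix()].
#' @param thr a `gate_thresholds`.
#' @param params a `normalization_params` (from the gated negative control).
#' @param blue_channel,red_channel channel names.
#' @param normalize divide the centered log values by the
#'   negative-control scale (`TRUE`, default) or center only (`FALSE`).
#' @return A `transformed_cells` data frame: `cell_id`, `blue_log`,
#'   `red_log`, `blue_norm`, `red_norm` (unclamped), `angle` (degrees),
#'   `intensity`, `timer_positive`, `quadrant`; sample id kept as an
#'   attribute.
#' @export
transform_sample <- function(sample, thr, params, blue_channel, red_channel,
                             normalize = TRUE) {
  blue_raw <- sample[[blue_channel]]
  red_raw <- sample[[red_channel]]
  if (is.null(blue_raw) || is.null(red_raw)) {
    stop_data("sample '", sample_id_of(sample), "' lacks Timer channel(s)")
  }
  blue_log <- log_transform(blue_raw, params$log_floor)
  red_log <- log_transform(red_raw, params$log_floor)
  if (normalize) {
    blue_norm <- normalize_channel(blue_log, params$blue_location, params$blue_scale)
    red_norm <- normalize_channel(red_log, params$red_location, params$red_scale)
  } else {
    blue_norm <- blue_log - params$blue_location
    red_norm <- red_log - params$red_location
  }
  positive <- classify_timer_positive(blue_raw, red_raw, thr)
  quadrant <- quadrant_classify(blue_raw, red_raw, thr)
  polar <- trig_transform(blue_norm, red_norm)
  polar$angle[!positive] <- NA_real_
  polar$intensity[!positive] <- NA_real_
  out <- data.frame(cell_id = seq_len(nrow(sample)),
                    blue_log = blue_log, red_log = red_log,
                    blue_norm = blue_norm, red_norm = red_norm,
                    angle = polar$angle, intensity = polar$intensity,
                    timer_positive = positive, quadrant = quadrant)
  structure(out, sample_id = sample_id_of(sample),
            class = c("transformed_cells", "data.frame"))
}

count_sample <- function(tc) {
  qc <- table(tc$quadrant)
  data.frame(sample_id = attr(tc, "sample_id"),
             n_total = nrow(tc),
             n_timer_positive = sum(tc$timer_positive),
             n_NegNeg = as.integer(qc[["NegNeg"]]),
             n_BluePosRedNeg = as.integer(qc[["BluePosRedNeg"]]),
             n_BluePosRedPos = as.integer(qc[["BluePosRedPos"]]),
             n_BlueNegRedPos = as.integer(qc[["BlueNegRedPos"]]),
             stringsAsFactors = FALSE)
}

#' Batch Timer transformation over a manifest
#'
#' The batch pipeline with a fixed stage order: (1) gating thresholds
#' from the negative control; (2) gate the negative control below both
#' thresholds; (3) normalization statistics from the gated negative
#' cells; (4) transform every sample — and the control itself — with the
#' same thresholds and parameters. When the manifest has an
#' `output_dir`, per-sample transformed tables, a parameters file, a
#' counts table, and the sample-definition file are written there as CSV.
#'
#' @param manifest a `sample_manifest` from [build_manifest()].
#' @param spec a [threshold_spec()].
#' @param method normalization scale, `"MAD"` (default) or `"SD"`.
#' @param normalize apply the scale division (see [transform_sample()]).
#' @param log_floor raw-unit floor for the log transform.
#' @param write write output CSVs to `manifest$output_dir`.
#' @return A `tocky_result`: list with `samples` (named list of
#'   `transformed_cells`), `params`, `thresholds`, `counts` (one row per
#'   file, control included), and `sample_definition`.
#' @export
timer_transform_batch <- function(manifest, spec = threshold_spec(),
                                  method = c("MAD", "SD"), normalize = TRUE,
                                  log_floor = 1,
                                  write = !is.null(manifest$output_dir)) {
  stopifnot(inherits(manifest, "sample_manifest"))
  method <- match.arg(method)
  entries <- manifest$entries
  neg_entry <- entries[entries$role == "negative_control", , drop = FALSE]
  if (nrow(neg_entry) != 1L) {
    stop_config("manifest must designate exactly one negative control")
  }
  bc <- manifest$blue_channel
  rc <- manifest$red_channel
  neg <- read_cell_matrix(neg_entry, manifest$common_variables,
                          required = c(bc, rc))
  thr <- compute_gate_thresholds(neg, spec, bc, rc)
  gated <- gate_negative_cells(neg, thr, bc, rc)
  params <- compute_normalization_params(gated, bc, rc, method = method,
                                         log_floor = log_floor)
  samples <- vector("list", nrow(entries))
  names(samples) <- entries$sample_id
  counts <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    entry <- entries[i, ]
    cm <- tryCatch(
      read_cell_matrix(entry, manifest$common_variables, required = c(bc, rc)),
      error = function(e) stop_data("sample '", entry$sample_id, "': ",
                                    conditionMessage(e)))
    if (nrow(cm) == 0L) stop_data("sample '", entry$sample_id,
                                  "' contains no cells (", entry$path, ")")
    samples[[i]] <- transform_sample(cm, thr, params, bc, rc,
                                     normalize = normalize)
    counts[[i]] <- count_sample(samples[[i]])
  }
  counts <- do.call(rbind, counts)
  counts <- cbind(counts[, "sample_id", drop = FALSE],
                  group = entries$group, role = entries$role,
                  counts[, -1, drop = FALSE])
  result <- structure(list(samples = samples, params = params,
                           thresholds = thr, counts = counts,
                           sample_definition = entries,
                           blue_channel = bc, red_channel = rc,
                           normalize = normalize),
                      class = "tocky_result")
  if (isTRUE(write)) write_tocky_result(result, manifest$output_dir)
  result
}

#' @export
print.tocky_result <- function(x, ...) {
  cat(sprintf("<tocky_result> %d sample(s); thresholds blue=%.4g red=%.4g; %s %s\n",
              length(x$samples), x$thresholds$blue, x$thresholds$red,
              x$params$method,
              if (x$normalize) "normalized" else "centered-only"))
  invisible(x)
}

#' Write batch outputs as CSV
#'
#' Emits one transformed table per sample
#' (`transformed_<sample_id>.csv`), a one-row `parameters.csv`
#' (thresholds, locations, scales, method, log floor, gate size), a
#' `counts.csv` and the `sample_definition.csv`. Floating-point columns
#' are written at 6 significant digits.
#'
#' @param result a `tocky_result`.
#' @param output_dir destination directory.
#' @return `output_dir`, invisibly.
#' @export
write_tocky_result <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(result$samples)) {
    df <- result$samples[[sid]]
    names(df)[names(df) == "angle"] <- "angle_deg"
    write_output_csv(df, file.path(output_dir,
                                   paste0("transformed_", sid, ".csv")))
  }
  p <- result$params
  write_output_csv(
    data.frame(blue_threshold = result$thresholds$blue,
               red_threshold = result$thresholds$red,
               blue_location = p$blue_location, blue_scale = p$blue_scale,
               red_location = p$red_location, red_scale = p$red_scale,
               method = p$method, log_floor = p$log_floor,
               n_gated_neg = p$n_gated_neg,
               normalize = result$normalize),
    file.path(output_dir, "parameters.csv"))
  write_output_csv(result$counts, file.path(output_dir, "counts.csv"))
  utils::write.csv(result$sample_definition,
                   file.path(output_dir, "sample_definition.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(output_dir)
}

#' Multiply the blue channel of a sample
#'
#' Simulates an acquisition-gain bias by scaling the raw Timer Blue
#' fluorescence by a positive factor while leaving every other channel
#' untouched. Used to probe the sensitivity of the Timer Angle to channel
#' imbalance and to verify that normalization cancels it.
#'
#' @param data a [cell_matrix()].
#' @param k positive multiplier.
#' @param blue_channel channel to scale.
#' @return A [cell_matrix()] with the blue column multiplied by `k`.
#' @export
apply_blue_multiplier <- function(data, k, blue_channel) {
  if (!is_scalar_number(k) || k <= 0) stop_config("multiplier k must be > 0")
  data[[blue_channel]] <- data[[blue_channel]] * k
  data
}
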