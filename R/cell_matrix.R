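#' Construct a per-cell channel table for one sample
#'
#' A `cell_matrix` is a plain data frame (rows = cells, columns = named
#' fluorescence channels, raw arbitrary units) carrying the sample id and a
#' count of rows dropped during ingestion as attributes. Raw values may be
#' non-positive; the log floor handles those downstream.
#'
#' @param values data frame or matrix of numeric channel values.
#' @param sample_id short unique sample identifier.
#' @param n_dropped number of rows removed during ingestion.
#' @return A data frame of class `cell_matrix`.
#' @export
cell_matrix <- function(values, sample_id, n_dropped = 0L) {
  values <- as.data.frame(values)
  if (!all(vapply(values, is.numeric, logical(1)))) {
    stop_data("cell_matrix requires all-numeric channel columns")
  }
  structure(values,
            sample_id = as.character(sample_id),
            n_dropped = as.integer(n_dropped),
            class = c("cell_matrix", "data.frame"))
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> sample '%s': %d cells x %d channels (%s)\n",
              attr(x, "sample_id"), nrow(x), ncol(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

sample_id_of <- function(x) attr(x, "sample_id")

#' Read a sample CSV into a cell matrix
#'
#' Reads one flow-software CSV export (comma-delimited, mandatory header
#' row, "." decimal), restricts it to the requested channels, and drops
#' rows whose blue/red values are missing or non-numeric. Original row
#' order is preserved; the number of dropped rows is recorded in the
#' `n_dropped` attribute and logged.
#'
#' @param entry a one-row data frame / list with `sample_id` and `path`
#'   (as produced by [build_manifest()]), or simply a file path.
#' @param variables character vector of channel names to retain.
#' @param required channels in which a missing value causes the row to be
#'   dropped (default: all of `variables`).
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(entry, variables, required = variables) {
  if (is.character(entry)) entry <- list(sample_id = basename(entry), path = entry)
  path <- as.character(entry$path)
  if (!file.exists(path)) stop_data("sample file does not exist: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_data("unparseable CSV '", path, "': ", conditionMessage(e)))
  missing_cols <- setdiff(variables, names(df))
  if (length(missing_cols) > 0) {
    stop_data("file '", path, "' lacks mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df <- df[, variables, drop = FALSE]
  # Coerce; non-numeric tokens become NA and are dropped below.
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  keep <- !Reduce(`|`, lapply(df[required], is.na), accumulate = FALSE)
  if (length(keep) == 0) keep <- logical(0)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    msg_log(sprintf("%s: dropped %d row(s) with missing/non-numeric values",
                    entry$sample_id, n_dropped))
  }
  cell_matrix(df[keep, , drop = FALSE], entry$sample_id, n_dropped = n_dropped)
}
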