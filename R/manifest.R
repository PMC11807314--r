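#' Discover sample CSV files in a directory
#'
#' Deterministic, lexicographically sorted listing of files matching a
#' glob pattern. An empty result is allowed (e.g. an over-restrictive
#' pattern); a nonexistent directory is a configuration error.
#'
#' @param directory path to search (non-recursive).
#' @param include_pattern glob, e.g. `"*.csv"`.
#' @return Character vector of full file paths, sorted.
#' @export
discover_files <- function(directory, include_pattern = "*.csv") {
  if (!dir.exists(directory)) {
    stop_config("directory does not exist: ", directory)
  }
  files <- list.files(directory,
                      pattern = utils::glob2rx(include_pattern),
                      full.names = TRUE)
  sort(files, method = "radix")
}

#' Build a sample manifest
#'
#' Assembles the set of sample files and the designated Timer-negative
#' control into a manifest, computes the channels common to every file
#' (the intersection of all header sets, control included), and checks
#' that the blue and red Timer channels are among them. Exactly one file
#' is the negative control.
#'
#' @param paths character vector of sample CSV paths (must include the
#'   negative control).
#' @param negative_control path of the Timer-negative control file.
#' @param blue_channel,red_channel exact header names of the immature
#'   (blue) and mature (red) Timer channels.
#' @param groups optional named character vector mapping sample_id to a
#'   group label (e.g. timepoint); unnamed samples get group `"unassigned"`.
#' @param output_dir directory where batch outputs and the serialized
#'   manifest will be written; created if needed. `NULL` to skip writing.
#' @return A `sample_manifest`: list with `entries` (data frame:
#'   sample_id, path, role, group), `common_variables`, `blue_channel`,
#'   `red_channel`, `output_dir`.
#' @export
build_manifest <- function(paths, negative_control, blue_channel, red_channel,
                           groups = NULL, output_dir = NULL) {
  paths <- as.character(paths)
  if (!(negative_control %in% paths)) {
    stop_config("negative_control '", negative_control,
                "' is not among the supplied paths")
  }
  if (identical(blue_channel, red_channel)) {
    stop_config("blue_channel and red_channel must be distinct")
  }
  sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(sample_ids)) {
    stop_config("duplicate sample_ids: ",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  headers <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_data("file does not exist: ", p)
    hdr <- tryCatch(names(utils::read.csv(p, nrows = 1, check.names = FALSE)),
                    error = function(e) stop_data("cannot read header of '", p,
                                                  "': ", conditionMessage(e)))
    if (length(hdr) == 0) stop_data("file '", p, "' has no header row")
    hdr
  })
  common <- Reduce(intersect, headers)
  for (ch in c(blue_channel, red_channel)) {
    if (!(ch %in% common)) {
      present <- vapply(headers, function(h) ch %in% h, logical(1))
      report <- paste(sprintf("%s: %s", basename(paths),
                              ifelse(present, "present", "MISSING")),
                      collapse = "; ")
      stop_config("channel '", ch, "' is not common to all files (", report, ")")
    }
  }
  role <- ifelse(paths == negative_control, "negative_control", "sample")
  group <- rep("unassigned", length(paths))
  if (!is.null(groups)) {
    hit <- sample_ids %in% names(groups)
    group[hit] <- unname(groups[sample_ids[hit]])
  }
  entries <- data.frame(sample_id = sample_ids, path = paths,
                        role = role, group = group,
                        stringsAsFactors = FALSE)
  manifest <- structure(list(entries = entries,
                             common_variables = common,
                             blue_channel = blue_channel,
                             red_channel = red_channel,
                             output_dir = output_dir),
                        class = "sample_manifest")
  if (!is.null(output_dir)) write_manifest(manifest, output_dir)
  manifest
}

#' @export
print.sample_manifest <- function(x, ...) {
  cat(sprintf("<sample_manifest> %d file(s), control '%s'\n",
              nrow(x$entries),
              x$entries$sample_id[x$entries$role == "negative_control"]))
  cat(sprintf("  channels (%d common): %s\n", length(x$common_variables),
              paste(x$common_variables, collapse = ", ")))
  cat(sprintf("  blue = '%s', red = '%s'\n", x$blue_channel, x$red_channel))
  invisible(x)
}

#' Serialize a manifest to plain-text files
#'
#' Writes the sample-definition file (`sample_definition.csv`: sample_id,
#' path, role, group), the common-variables list (`common_variables.txt`,
#' one channel per line), and the blue/red channel designation
#' (`timer_channels.txt`) into `output_dir`.
#'
#' @param manifest a `sample_manifest`.
#' @param output_dir destination directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_manifest <- function(manifest, output_dir = manifest$output_dir) {
  stopifnot(inherits(manifest, "sample_manifest"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest$entries,
                   file.path(output_dir, "sample_definition.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(manifest$common_variables,
             file.path(output_dir, "common_variables.txt"))
  writeLines(c(paste0("blue_channel=", manifest$blue_channel),
               paste0("red_channel=", manifest$red_channel)),
             file.path(output_dir, "timer_channels.txt"))
  invisible(output_dir)
}

#' Read a serialized manifest back
#'
#' Inverse of [write_manifest()]; a round trip returns an identical
#' manifest.
#'
#' @param output_dir directory written by [write_manifest()].
#' @return A `sample_manifest`.
#' @export
read_manifest <- function(output_dir) {
  def_path <- file.path(output_dir, "sample_definition.csv")
  if (!file.exists(def_path)) stop_config("no sample_definition.csv in ", output_dir)
  entries <- utils::read.csv(def_path, stringsAsFactors = FALSE)
  common <- readLines(file.path(output_dir, "common_variables.txt"))
  chans <- readLines(file.path(output_dir, "timer_channels.txt"))
  kv <- strsplit(chans, "=", fixed = TRUE)
  names(kv) <- vapply(kv, `[`, "", 1L)
  structure(list(entries = entries,
                 common_variables = common,
                 blue_channel = kv[["blue_channel"]][2],
                 red_channel = kv[["red_channel"]][2],
                 output_dir = output_dir),
            class = "sample_manifest")
}
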