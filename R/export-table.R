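# Delimited-table export/import for numeric tracks. Waveforms are exported
# via EDF (a per-sample table of 500 Hz data would explode row counts).

#' Export options for delimited tables
#'
#' @param interval_s Output grid step in seconds (> 0).
#' @param missing_policy `"blank"` (a grid cell with no sample is left empty)
#'   or `"carry-forward"` (filled with the latest sample no older than
#'   `max_staleness_s`).
#' @param max_staleness_s Maximum age of a carried-forward sample, seconds.
#' @param dialect `"comma"` (csv) or `"tab"` (tsv).
#' @param time_format `"relative"` writes seconds since `rec_start`;
#'   `"iso"` writes ISO-8601 UTC timestamps.
#' @return An `export_options` list.
#' @export
export_options <- function(interval_s = 1, missing_policy = c("blank", "carry-forward"),
                           max_staleness_s = 0, dialect = c("comma", "tab"),
                           time_format = c("relative", "iso")) {
  if (interval_s <= 0) stop("interval_s must be > 0")
  if (max_staleness_s < 0) stop("max_staleness_s must be >= 0")
  structure(list(interval_s = interval_s,
                 missing_policy = match.arg(missing_policy),
                 max_staleness_s = max_staleness_s,
                 dialect = match.arg(dialect),
                 time_format = match.arg(time_format)),
            class = "export_options")
}

# Grid resampling of one numeric track: for each grid time the latest sample
# not older than `staleness` (0 = only exact hits), NA otherwise.
grid_sample <- function(samples, grid, staleness) {
  idx <- findInterval(grid + 1e-9, samples$time)
  out <- rep(NA_real_, length(grid))
  ok <- idx >= 1L
  age <- grid[ok] - samples$time[idx[ok]]
  ok2 <- age <= staleness + 1e-9
  out[which(ok)[ok2]] <- samples$value[idx[ok][ok2]]
  out
}

#' Export numeric tracks to a delimited table
#'
#' Rows are grid times from `rec_start` to the last numeric sample at
#' `interval_s` steps; one column per numeric track (key `device/name`).
#' Cells follow the missing-value policy; wave tracks are excluded.
#'
#' @param recording A `vital_recording` with at least one numeric track.
#' @param path Output file path.
#' @param options An [export_options()].
#' @return Invisibly, the exported `data.frame`. Warns (and writes an empty
#'   table) when the recording has no numeric tracks.
#' @export
export_table <- function(recording, path, options = export_options()) {
  num <- recording$tracks[vapply(recording$tracks, function(tr)
    tr$kind == "numeric", logical(1))]
  sep <- if (options$dialect == "comma") "," else "\t"
  if (length(num) == 0L) {
    warning("recording has no numeric tracks; writing an empty table")
    utils::write.table(data.frame(time = numeric()), path, sep = sep,
                       row.names = FALSE, quote = FALSE)
    return(invisible(data.frame(time = numeric())))
  }
  last <- max(vapply(num, function(tr)
    if (nrow(tr$samples)) tr$samples$time[nrow(tr$samples)] else -Inf,
    numeric(1)))
  grid <- if (is.finite(last) && last >= recording$rec_start)
    seq(recording$rec_start, last, by = options$interval_s) else numeric()
  staleness <- if (options$missing_policy == "carry-forward")
    options$max_staleness_s else 0
  cols <- lapply(num, function(tr) grid_sample(tr$samples, grid, staleness))
  df <- data.frame(time = grid - if (options$time_format == "relative")
    recording$rec_start else 0)
  if (options$time_format == "iso")
    df$time <- format(as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                      "%Y-%m-%dT%H:%M:%OS3")
  for (k in names(cols)) df[[k]] <- cols[[k]]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(df)
}

#' Import a delimited table as a recording
#'
#' Each non-time column becomes one numeric track (device `"CSV"`, parameter
#' = column header). The time column is auto-detected as ISO-8601 absolute
#' timestamps or numeric seconds relative to 0; unparseable cells are skipped
#' and counted.
#'
#' @param path Input file.
#' @param time_column Name of the time column (default: first column).
#' @param dialect `"comma"`, `"tab"`, or `NULL` to infer from the extension.
#' @return A `vital_recording` with attributes `n_skipped` (unparseable
#'   cells) and `time_mode` (`"absolute"` or `"relative"`).
#' @export
import_table <- function(path, time_column = NULL, dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tab" else "comma"
  sep <- if (dialect == "comma") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 1L) stop("table has no columns")
  if (is.null(time_column)) time_column <- names(df)[1L]
  if (!time_column %in% names(df))
    stop("no time column '", time_column, "' in '", path, "'")
  raw_t <- df[[time_column]]
  iso <- tryCatch(
    suppressWarnings(as.POSIXct(raw_t, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS"))),
    error = function(e) rep(as.POSIXct(NA), length(raw_t)))
  if (length(iso) && all(!is.na(iso))) {
    times <- as.numeric(iso)
    time_mode <- "absolute"
  } else {
    times <- suppressWarnings(as.numeric(raw_t))
    time_mode <- "relative"
  }
  good_t <- !is.na(times)
  n_skipped <- sum(!good_t)
  tracks <- list()
  for (col in setdiff(names(df), time_column)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    keep <- good_t & !is.na(vals) & nzchar(df[[col]])
    n_skipped <- n_skipped + sum(good_t & !keep)
    key <- strsplit(col, "/", fixed = TRUE)[[1L]]
    device <- if (length(key) >= 2L) key[1L] else "CSV"
    name <- if (length(key) >= 2L) paste(key[-1L], collapse = "/") else col
    samples <- data.frame(time = times[keep], value = vals[keep])
    samples <- samples[order(samples$time), , drop = FALSE]
    samples <- samples[!duplicated(samples$time), , drop = FALSE]
    tracks[[length(tracks) + 1L]] <- numeric_track(device, name, "", samples)
  }
  message(sprintf("imported %d tracks from '%s' (time mode: %s, %d cells skipped)",
                  length(tracks), path, time_mode, n_skipped))
  rec <- vital_recording(tracks, metadata = c(source = basename(path)))
  attr(rec, "n_skipped") <- n_skipped
  attr(rec, "time_mode") <- time_mode
  rec
}
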