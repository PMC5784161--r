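# Batch file utilities: de-identification, multi-file track extraction,
# case listing, and the offline automatic-recording loop.

# De-identification anchor: 2100-01-01T00:00:00 UTC.
DEID_ANCHOR <- 4102444800

# Rebase a track's times onto a new start: new = anchor + (t - old_start).
# Computing through the relative offset (rather than adding one big shift)
# keeps relative times exact at the container's stored precision.
rebase_track <- function(tr, old_start, anchor) {
  mv <- function(t) anchor + (t - old_start)
  if (tr$kind == "wave") {
    tr$blocks <- lapply(tr$blocks, function(b)
      wave_block(mv(b$start), b$srate, b$counts))
  } else if (tr$kind == "numeric") {
    tr$samples$time <- mv(tr$samples$time)
  } else {
    tr$events$time <- mv(tr$events$time)
  }
  tr
}

#' De-identify a recording
#'
#' Moves the record start time to the fixed anchor 2100-01-01T00:00:00 UTC
#' and shifts every timestamp by the same amount, so all inter-sample
#' intervals are preserved exactly. Metadata fields other than the device
#' roster and format version are cleared (event text is left untouched;
#' screen free text for names before sharing).
#'
#' @param recording A `vital_recording`.
#' @param fields_kept Metadata keys to retain; everything else is blanked.
#' @return The de-identified `vital_recording` (idempotent).
#' @export
deidentify <- function(recording,
                       fields_kept = c("devices", "format_version")) {
  tracks <- lapply(recording$tracks, rebase_track,
                   old_start = recording$rec_start, anchor = DEID_ANCHOR)
  md <- recording$metadata
  md[!names(md) %in% fields_kept] <- ""
  vital_recording(tracks, rec_start = DEID_ANCHOR, metadata = md)
}

#' Extract tracks from many container files at once
#'
#' Files are first probed with [scan_tracks()]; files lacking any track that
#' matches the query are skipped without decoding a single payload byte, and
#' matching files are decoded selectively (only the matching numeric tracks),
#' so extraction cost scales with the extracted data, not file payloads.
#' Unreadable files are recorded in the report and processing continues.
#'
#' @param paths Container file paths.
#' @param track_query Glob pattern(s) matched against `device/name` keys
#'   (`"*"` = every numeric track).
#' @param combine Return one combined long table instead of one per file.
#' @return A list with `tables` (per-file, or `combined`: columns `file`,
#'   `time`, `key`, `value`) and `report` (`file`, `status`, `n_matched`,
#'   `payload_bytes_decoded`).
#' @export
batch_extract <- function(paths, track_query = "*", combine = FALSE) {
  rx <- paste(vapply(track_query, utils::glob2rx, character(1)), collapse = "|")
  tables <- list()
  report <- data.frame(file = character(), status = character(),
                       n_matched = integer(), payload_bytes_decoded = numeric(),
                       wave_bytes_decoded = numeric(), stringsAsFactors = FALSE)
  note <- function(file, status, n = 0L, bytes = 0, wave_bytes = 0) {
    report[nrow(report) + 1L, ] <<- list(file, status, n, bytes, wave_bytes)
  }
  for (p in paths) {
    dir <- tryCatch(scan_tracks(p), error = function(e) e)
    if (inherits(dir, "error")) { note(p, "error"); next }
    matched <- dir$key[grepl(rx, dir$key) & dir$kind == "numeric"]
    if (length(matched) == 0L) { note(p, "skipped"); next }
    rec <- tryCatch(read_vital(p, tracks = matched), error = function(e) e)
    if (inherits(rec, "error")) { note(p, "error"); next }
    rows <- lapply(matched, function(k) {
      s <- rec$tracks[[k]]$samples
      if (nrow(s)) data.frame(file = p, time = s$time, key = k,
                              value = s$value, stringsAsFactors = FALSE)
    })
    tables[[p]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    note(p, "ok", length(matched), attr(rec, "payload_bytes_decoded"),
         attr(rec, "wave_payload_bytes_decoded"))
  }
  out <- list(report = report)
  if (combine) out$combined <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  else out$tables <- tables
  out
}

#' List case files in a directory tree
#'
#' One summary row per container file (dated subfolders are traversed
#' recursively): start time, duration from track extents, device roster, and
#' presence of the key heart-rate/oxygen-saturation tracks. Non-container or
#' corrupt files are skipped with a note.
#'
#' @param directory Root directory.
#' @param hr_param,spo2_param Key-track parameter names to check for.
#' @return `data.frame` with columns `file`, `start`, `duration_s`,
#'   `n_tracks`, `devices`, `has_hr`, `has_spo2`; attribute `skipped` lists
#'   files that could not be read.
#' @export
list_cases <- function(directory, hr_param = "HR", spo2_param = "SPO2") {
  files <- list.files(directory, pattern = "\\.vital$", recursive = TRUE,
                      full.names = TRUE)
  rows <- list()
  skipped <- character()
  for (f in files) {
    rec <- tryCatch(suppressWarnings(read_vital(f)), error = function(e) e)
    if (inherits(rec, "error")) { skipped <- c(skipped, f); next }
    firsts <- vapply(rec$tracks, track_first_time, numeric(1))
    lasts <- vapply(rec$tracks, track_last_time, numeric(1))
    dur <- if (all(is.na(lasts))) 0 else
      max(lasts, na.rm = TRUE) - min(firsts, na.rm = TRUE)
    params <- vapply(rec$tracks, `[[`, character(1), "name")
    rows[[length(rows) + 1L]] <- data.frame(
      file = f,
      start = as.POSIXct(rec$rec_start, origin = "1970-01-01", tz = "UTC"),
      duration_s = dur, n_tracks = length(rec$tracks),
      devices = paste(sort(unique(vapply(rec$tracks, `[[`, character(1),
                                         "device"))), collapse = ","),
      has_hr = hr_param %in% params, has_spo2 = spo2_param %in% params,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), start = as.POSIXct(character(), tz = "UTC"),
               duration_s = numeric(), n_tracks = integer(),
               devices = character(), has_hr = logical(), has_spo2 = logical())
  attr(out, "skipped") <- skipped
  out
}

#' Run the offline automatic-recording loop
#'
#' Wires the simulator, segmenter and container writer together: segments a
#' message stream into cases and writes one container file per case into a
#' folder named after the case date (`YYYY-MM-DD/HHMMSS.vital`), emulating
#' the automatic per-case recording workflow.
#'
#' @param stream A message stream (see [generate_stream()]).
#' @param out_dir Output root directory.
#' @param config A [segmenter_config()].
#' @return A list with `boundaries` and `files` (paths written).
#' @export
record_session <- function(stream, out_dir, config = segmenter_config()) {
  seg <- segment_stream(stream, config)
  files <- character()
  for (k in seq_along(seg$boundaries)) {
    rows <- which(!is.na(seg$assignment) & seg$assignment == k)
    if (!length(rows)) next
    sub <- stream[rows, , drop = FALSE]
    for (a in c("roster", "rec_start")) attr(sub, a) <- attr(stream, a)
    attr(sub, "rec_start") <- min(sub$time)
    rec <- stream_to_recording(sub)
    day <- format(as.POSIXct(rec$rec_start, origin = "1970-01-01", tz = config$tz),
                  "%Y-%m-%d")
    dir.create(file.path(out_dir, day), recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, day,
                      paste0(format(as.POSIXct(rec$rec_start, origin = "1970-01-01",
                                               tz = config$tz), "%H%M%S"),
                             ".vital"))
    write_vital(rec, path)
    files <- c(files, path)
  }
  list(boundaries = seg$boundaries, files = files)
}
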