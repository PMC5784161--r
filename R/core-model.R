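#' @keywords internal
"_PACKAGE"

# Track kinds and their wire codes (container format version 1).
KIND_CODES <- c(wave = 1L, numeric = 2L, event = 3L)

#' Construct a time point
#'
#' Time points are plain numeric seconds since the Unix epoch. This helper
#' validates the value; everywhere else in the package bare numerics are
#' accepted.
#'
#' @param epoch_s Seconds since 1970-01-01 00:00:00 UTC (finite, >= 0).
#' @return A numeric scalar.
#' @export
time_point <- function(epoch_s) {
  epoch_s <- as.numeric(epoch_s)
  if (length(epoch_s) != 1L || !is.finite(epoch_s) || epoch_s < 0)
    stop("time point must be a finite non-negative number of epoch seconds")
  epoch_s
}

#' Construct a waveform sample block
#'
#' A block is a contiguous run of raw ADC counts at a fixed sampling rate.
#' Gaps in acquisition start a new block; counts are stored as passed from
#' the digitiser, with physical conversion factors kept on the owning track.
#'
#' @param start Start time (epoch seconds) of the first sample.
#' @param srate Sampling rate in samples/second (> 0).
#' @param counts Integer vector of ADC counts (non-empty).
#' @return A `wave_block` object.
#' @export
wave_block <- function(start, srate, counts) {
  if (!is.numeric(srate) || srate <= 0) stop("srate must be > 0")
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("a wave block must contain at least one count")
  if (anyNA(counts)) stop("counts must not contain NA")
  structure(list(start = as.numeric(start), srate = as.numeric(srate),
                 counts = counts),
            class = "wave_block")
}

# End time of the last sample in a block.
block_end <- function(b) b$start + (length(b$counts) - 1L) / b$srate

#' Construct a waveform track
#'
#' @param device Device name (e.g. `"Solar8000"`).
#' @param name Parameter name (e.g. `"ECG_II"`).
#' @param unit Physical unit label.
#' @param gain Physical units per count (non-zero).
#' @param offset Physical offset: value = gain * count + offset.
#' @param digital_min,digital_max Integer count bounds of the digitiser.
#' @param srate Nominal sampling rate (samples/second).
#' @param blocks List of [wave_block()] objects, time-sorted, non-overlapping.
#' @return A `vital_track` of kind `"wave"`.
#' @export
wave_track <- function(device, name, unit = "", gain = 1, offset = 0,
                       digital_min = 0L, digital_max = 1023L,
                       srate, blocks = list()) {
  if (gain == 0) stop("wave tracks require a non-zero gain")
  tr <- structure(list(device = as.character(device), name = as.character(name),
                       kind = "wave", unit = as.character(unit),
                       gain = as.numeric(gain), offset = as.numeric(offset),
                       digital_min = as.integer(digital_min),
                       digital_max = as.integer(digital_max),
                       srate = as.numeric(srate), blocks = blocks),
                  class = "vital_track")
  validate_track(tr)
  tr
}

#' Construct a numeric (slow parameter) track
#'
#' @inheritParams wave_track
#' @param samples `data.frame` with columns `time` (epoch seconds, strictly
#'   increasing) and `value` (numeric).
#' @return A `vital_track` of kind `"numeric"`.
#' @export
numeric_track <- function(device, name, unit = "",
                          samples = data.frame(time = numeric(), value = numeric())) {
  tr <- structure(list(device = as.character(device), name = as.character(name),
                       kind = "numeric", unit = as.character(unit),
                       gain = 1, offset = 0,
                       digital_min = NA_integer_, digital_max = NA_integer_,
                       srate = NA_real_,
                       samples = data.frame(time = as.numeric(samples$time),
                                            value = as.numeric(samples$value))),
                  class = "vital_track")
  validate_track(tr)
  tr
}

#' Construct an event (annotation) track
#'
#' @inheritParams wave_track
#' @param events `data.frame` with columns `time` (epoch seconds) and `text`.
#' @return A `vital_track` of kind `"event"`.
#' @export
event_track <- function(device, name,
                        events = data.frame(time = numeric(), text = character())) {
  tr <- structure(list(device = as.character(device), name = as.character(name),
                       kind = "event", unit = "",
                       gain = 1, offset = 0,
                       digital_min = NA_integer_, digital_max = NA_integer_,
                       srate = NA_real_,
                       events = data.frame(time = as.numeric(events$time),
                                           text = as.character(events$text),
                                           stringsAsFactors = FALSE)),
                  class = "vital_track")
  validate_track(tr)
  tr
}

#' Track key
#'
#' Tracks are keyed by `"device/name"` throughout the package (track
#' directories, merge conflicts, filter inputs, CLI queries).
#'
#' @param track A `vital_track`, or a device name when `name` is given.
#' @param name Optional parameter name.
#' @return A character key.
#' @export
track_key <- function(track, name = NULL) {
  if (is.null(name)) paste(track$device, track$name, sep = "/")
  else paste(track, name, sep = "/")
}

#' Validate a track against its kind invariants
#'
#' Wave blocks must be non-empty, time-sorted, non-overlapping and within the
#' digitiser range; numeric samples strictly time-sorted; each kind carries
#' only its own payload.
#'
#' @param track A `vital_track`.
#' @return The track, invisibly; errors name the offending track.
#' @export
validate_track <- function(track) {
  key <- track_key(track)
  if (!track$kind %in% names(KIND_CODES))
    stop(sprintf("track '%s': unknown kind '%s'", key, track$kind))
  if (track$kind == "wave") {
    if (!is.finite(track$gain) || track$gain == 0)
      stop(sprintf("track '%s': wave gain must be non-zero", key))
    if (!is.finite(track$srate) || track$srate <= 0)
      stop(sprintf("track '%s': wave srate must be > 0", key))
    prev_end <- -Inf
    for (b in track$blocks) {
      if (!inherits(b, "wave_block"))
        stop(sprintf("track '%s': blocks must be wave_block objects", key))
      if (b$start <= prev_end)
        stop(sprintf("track '%s': wave blocks overlap or are unsorted", key))
      if (any(b$counts < track$digital_min) || any(b$counts > track$digital_max))
        stop(sprintf("track '%s': counts outside digital range [%d, %d]",
                     key, track$digital_min, track$digital_max))
      prev_end <- block_end(b)
    }
  } else if (track$kind == "numeric") {
    tt <- track$samples$time
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("track '%s': numeric samples must be strictly time-sorted", key))
  } else {
    tt <- track$events$time
    if (is.unsorted(tt))
      stop(sprintf("track '%s': events must be time-sorted", key))
  }
  invisible(track)
}

#' Construct a recording
#'
#' A recording is one case file: a set of tracks keyed by `device/name`, a
#' record start time, and free-form string metadata. By design no site
#' identifiers are added to the metadata.
#'
#' @param tracks List of `vital_track` objects (keys must be unique).
#' @param rec_start Record start time, epoch seconds; defaults to the earliest
#'   sample time across tracks (0 for an empty recording).
#' @param metadata Named character vector of free-form metadata.
#' @return A `vital_recording`.
#' @export
vital_recording <- function(tracks = list(), rec_start = NULL,
                            metadata = character()) {
  keys <- vapply(tracks, track_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate track keys: ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(tracks) <- keys
  if (is.null(rec_start)) {
    t0 <- suppressWarnings(min(vapply(tracks, function(tr) {
      ft <- track_first_time(tr)
      if (is.na(ft)) Inf else ft
    }, numeric(1)), Inf))
    rec_start <- if (is.finite(t0)) t0 else 0
  }
  md <- as.character(metadata)
  names(md) <- names(metadata)
  rec <- structure(list(rec_start = as.numeric(rec_start), tracks = tracks,
                        metadata = md),
                   class = "vital_recording")
  validate_recording(rec)
  rec
}

track_first_time <- function(tr) {
  switch(tr$kind,
    wave = if (length(tr$blocks)) tr$blocks[[1L]]$start else NA_real_,
    numeric = if (nrow(tr$samples)) tr$samples$time[1L] else NA_real_,
    event = if (nrow(tr$events)) tr$events$time[1L] else NA_real_)
}

track_last_time <- function(tr) {
  switch(tr$kind,
    wave = if (length(tr$blocks)) block_end(tr$blocks[[length(tr$blocks)]]) else NA_real_,
    numeric = if (nrow(tr$samples)) tr$samples$time[nrow(tr$samples)] else NA_real_,
    event = if (nrow(tr$events)) tr$events$time[nrow(tr$events)] else NA_real_)
}

#' Validate a recording
#'
#' Checks track validity, key uniqueness, and that no sample precedes
#' `rec_start`.
#'
#' @param rec A `vital_recording`.
#' @return The recording, invisibly. Errors list all offending tracks.
#' @export
validate_recording <- function(rec) {
  bad <- character()
  for (tr in rec$tracks) {
    ok <- tryCatch({ validate_track(tr); TRUE }, error = function(e) FALSE)
    ft <- track_first_time(tr)
    if (!ok || (!is.na(ft) && ft < rec$rec_start - 1e-9))
      bad <- c(bad, track_key(tr))
  }
  if (length(bad))
    stop("invalid recording; offending tracks: ", paste(bad, collapse = ", "))
  invisible(rec)
}

#' Describe an analog-to-digital converter
#'
#' @param n_bits Resolution in bits (>= 1).
#' @param v_min,v_max Measurement range in volts (`v_min < v_max`).
#' @return An `adc_spec` with derived `gain` (volts/count) and `offset` such
#'   that count 0 maps to `v_min` and the top count to `v_max` (endpoints
#'   inclusive).
#' @export
adc_spec <- function(n_bits = 10L, v_min = -5, v_max = 5) {
  if (n_bits < 1L) stop("n_bits must be >= 1")
  if (v_min >= v_max) stop("v_min must be < v_max")
  top <- 2L^as.integer(n_bits) - 1L
  structure(list(n_bits = as.integer(n_bits), v_min = v_min, v_max = v_max,
                 digital_min = 0L, digital_max = top,
                 gain = (v_max - v_min) / top, offset = v_min),
            class = "adc_spec")
}

#' Convert ADC counts to physical values
#'
#' Physical value = `gain * count + offset`, using the conversion factors
#' stored on the track. The mapping is exactly invertible for non-zero gain.
#'
#' @param count Integer count(s) within the track's digital range.
#' @param track The owning `vital_track` (wave kind).
#' @return Physical value(s) in `track$unit`.
#' @export
to_physical <- function(count, track) {
  if (any(count < track$digital_min | count > track$digital_max))
    stop(sprintf("count outside digital range [%d, %d] of track '%s'",
                 track$digital_min, track$digital_max, track_key(track)))
  track$gain * count + track$offset
}

#' Convert physical values to ADC counts
#'
#' Inverse of [to_physical()], rounding to the nearest count and clipping to
#' the digital range.
#'
#' @param value Physical value(s) in `track$unit`.
#' @param track The owning `vital_track`.
#' @return Integer counts.
#' @export
from_physical <- function(value, track) {
  cnt <- as.integer(round((value - track$offset) / track$gain))
  pmin(pmax(cnt, track$digital_min), track$digital_max)
}

#' Summarise a track
#'
#' Backs the `trks` utility: sample counts, extent, effective rate, physical
#' range. The effective rate of a wave track is total samples divided by
#' covered time, with gaps excluded.
#'
#' @param track A `vital_track`.
#' @return A list with `key`, `kind`, `n`, `first_time`, `last_time`,
#'   `rate` (waves; numerics report `n / span`), `phys_min`, `phys_max`.
#' @export
track_stats <- function(track) {
  out <- list(key = track_key(track), kind = track$kind, n = 0L,
              first_time = NA_real_, last_time = NA_real_, rate = NA_real_,
              phys_min = NA_real_, phys_max = NA_real_)
  if (track$kind == "wave") {
    ns <- vapply(track$blocks, function(b) length(b$counts), integer(1))
    out$n <- sum(ns)
    if (out$n > 0L) {
      out$first_time <- track$blocks[[1L]]$start
      out$last_time <- block_end(track$blocks[[length(track$blocks)]])
      covered <- sum(ns / track$srate)  # each sample covers 1/srate seconds
      out$rate <- out$n / covered
      rng <- range(vapply(track$blocks, function(b) range(b$counts), numeric(2)))
      out$phys_min <- to_physical(rng[1L], track)
      out$phys_max <- to_physical(rng[2L], track)
    }
  } else if (track$kind == "numeric") {
    out$n <- nrow(track$samples)
    if (out$n > 0L) {
      out$first_time <- track$samples$time[1L]
      out$last_time <- track$samples$time[out$n]
      span <- out$last_time - out$first_time
      if (span > 0) out$rate <- (out$n - 1L) / span
      out$phys_min <- min(track$samples$value)
      out$phys_max <- max(track$samples$value)
    }
  } else {
    out$n <- nrow(track$events)
    if (out$n > 0L) {
      out$first_time <- track$events$time[1L]
      out$last_time <- track$events$time[out$n]
    }
  }
  out
}

#' @export
print.vital_track <- function(x, ...) {
  s <- track_stats(x)
  cat(sprintf("<vital_track %s [%s]%s n=%d>\n", s$key, x$kind,
              if (x$kind == "wave") sprintf(" %g Hz", x$srate) else "", s$n))
  invisible(x)
}

#' @export
print.vital_recording <- function(x, ...) {
  cat(sprintf("<vital_recording: %d tracks, start %s>\n", length(x$tracks),
              format(as.POSIXct(x$rec_start, origin = "1970-01-01", tz = "UTC"))))
  for (tr in x$tracks) print(tr)
  invisible(x)
}
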