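# Automatic case segmentation: a case starts when heart-rate and oxygen-
# saturation messages are each seen more than `start_count_threshold` times
# within a trailing `start_window_s` window, and closes
# `stop_timeout_s` after the last of the two signals was seen.

#' Segmenter configuration
#'
#' Defaults implement the automatic-recording rule: a new case starts when
#' both the heart-rate and the oxygen-saturation signal have arrived more
#' than five times within one minute, and stops 10 minutes after both
#' signals disappear.
#'
#' @param start_count_threshold Messages per signal that must be strictly
#'   exceeded within the window (default 5: the 6th message triggers).
#' @param start_window_s Trailing window for the start count, seconds.
#' @param stop_timeout_s Silence after the last HR/SpO2 message that closes a
#'   case, seconds.
#' @param delete_between_cases Discard messages outside all case intervals
#'   during [segment_stream()] (otherwise they land in a residual bucket).
#' @param split_by_date Close a case crossing midnight at 00:00:00 and
#'   immediately open a new one (fragments rejoin with [merge_recordings()]).
#' @param hr_param,spo2_param Parameter names recognised as the heart-rate
#'   and oxygen-saturation signals.
#' @param tz Recorder clock time zone used for the midnight rule.
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(start_count_threshold = 5L, start_window_s = 60,
                             stop_timeout_s = 600,
                             delete_between_cases = FALSE,
                             split_by_date = FALSE,
                             hr_param = "HR", spo2_param = "SPO2",
                             tz = "UTC") {
  if (start_count_threshold <= 0 || start_window_s <= 0 || stop_timeout_s <= 0)
    stop("segmenter thresholds must be positive")
  structure(list(start_count_threshold = as.integer(start_count_threshold),
                 start_window_s = as.numeric(start_window_s),
                 stop_timeout_s = as.numeric(stop_timeout_s),
                 delete_between_cases = isTRUE(delete_between_cases),
                 split_by_date = isTRUE(split_by_date),
                 hr_param = hr_param, spo2_param = spo2_param, tz = tz),
            class = "segmenter_config")
}

next_midnight <- function(t, tz) {
  d <- as.POSIXct(trunc(as.POSIXct(t, origin = "1970-01-01", tz = tz), "days"))
  as.numeric(d) + 86400
}

#' Create a streaming segmenter
#'
#' An event-driven state machine fed one message at a time (no polling
#' clock). The sliding start window is evaluated at each message arrival.
#'
#' @param config A [segmenter_config()].
#' @return A `segmenter` object; see [feed()] and [advance()].
#' @export
new_segmenter <- function(config = segmenter_config()) {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$hr_times <- numeric()       # trailing-window buffers
  e$spo2_times <- numeric()
  e$last_hr <- -Inf
  e$last_spo2 <- -Inf
  e$in_case <- FALSE
  e$case_start <- NA_real_
  e$case_day_end <- Inf         # next midnight while a case is open
  e$last_time <- -Inf
  class(e) <- "segmenter"
  e
}

close_case <- function(seg, end, reason) {
  ev <- list(type = "case-closed",
             boundary = case_boundary(seg$case_start, end, reason))
  seg$in_case <- FALSE
  seg$case_start <- NA_real_
  seg$case_day_end <- Inf
  ev
}

open_case <- function(seg, start, reason = "threshold-met") {
  seg$in_case <- TRUE
  seg$case_start <- start
  seg$case_day_end <- if (seg$config$split_by_date)
    next_midnight(start, seg$config$tz) else Inf
  list(type = "case-started",
       boundary = case_boundary(start, NA_real_, NA_character_, reason))
}

case_boundary <- function(start, end, end_reason, start_reason = "threshold-met") {
  structure(list(case_start = start, case_end = end,
                 start_reason = start_reason, end_reason = end_reason),
            class = "case_boundary")
}

# Clock-only processing shared by feed() and advance(): emits the closures
# (timeout, date-split) implied by time reaching `now`.
advance_clock <- function(seg, now) {
  events <- list()
  cfg <- seg$config
  repeat {
    if (!seg$in_case) break
    last_sig <- max(seg$last_hr, seg$last_spo2)
    close_t <- last_sig + cfg$stop_timeout_s
    if (seg$case_day_end <= now && seg$case_day_end < close_t) {
      midnight <- seg$case_day_end
      events[[length(events) + 1L]] <- close_case(seg, midnight, "date-split")
      events[[length(events) + 1L]] <- open_case(seg, midnight, "date-split")
      next
    }
    if (now - last_sig >= cfg$stop_timeout_s) {
      events[[length(events) + 1L]] <- close_case(seg, close_t, "timeout")
      next
    }
    break
  }
  events
}

#' Feed one message to the segmenter
#'
#' @param seg A [new_segmenter()] object.
#' @param time Message time, epoch seconds (non-decreasing across calls).
#' @param key Track key (`device/name`); the name part is matched against the
#'   configured HR/SpO2 parameter names.
#' @param value Message payload (unused by the state machine).
#' @return List of state events, each a list with `type`
#'   (`"case-started"`/`"case-closed"`) and `boundary` (a `case_boundary`).
#' @export
feed <- function(seg, time, key, value = NA) {
  if (time < seg$last_time)
    stop(sprintf("message at t=%.3f arrives after t=%.3f: stream must be time-ordered",
                 time, seg$last_time))
  seg$last_time <- time
  cfg <- seg$config
  events <- advance_clock(seg, time)

  param <- sub("^.*/", "", key)
  w0 <- time - cfg$start_window_s
  if (identical(param, cfg$hr_param)) {
    seg$hr_times <- c(seg$hr_times[seg$hr_times > w0], time)
    seg$last_hr <- time
  } else if (identical(param, cfg$spo2_param)) {
    seg$spo2_times <- c(seg$spo2_times[seg$spo2_times > w0], time)
    seg$last_spo2 <- time
  } else {
    return(events)
  }

  if (!seg$in_case) {
    n_hr <- sum(seg$hr_times > w0)
    n_spo2 <- sum(seg$spo2_times > w0)
    if (n_hr > cfg$start_count_threshold && n_spo2 > cfg$start_count_threshold)
      events[[length(events) + 1L]] <- open_case(seg, time)
  }
  events
}

#' Advance the segmenter clock without a message
#'
#' Models continued silence: emits the case closure once the timeout (or a
#' midnight date-split) is reached.
#'
#' @inheritParams feed
#' @param time Current clock time, epoch seconds.
#' @return List of state events (possibly empty).
#' @export
advance <- function(seg, time) {
  if (time < seg$last_time)
    stop("clock must not run backwards")
  seg$last_time <- time
  advance_clock(seg, time)
}

#' Finalise a segmenter at end of stream
#'
#' Closes any open case. If the stream simply ends, the closure reason is
#' `"stream-end"` and the case ends at the final clock time; if the silence
#' already exceeded the timeout the normal timeout closure is emitted.
#'
#' @inheritParams advance
#' @param time End-of-stream clock time; defaults to the last time seen.
#' @return List of state events.
#' @export
finalize_segmenter <- function(seg, time = seg$last_time) {
  events <- advance(seg, max(time, seg$last_time))
  if (seg$in_case)
    events[[length(events) + 1L]] <- close_case(seg, seg$last_time, "stream-end")
  events
}

#' Segment a message stream into cases
#'
#' Batch driver over [feed()]: runs the state machine over a time-sorted
#' stream and assigns every message to a case (or, unless
#' `delete_between_cases` is set, to a residual bucket). Messages buffered in
#' the trailing start window preceding a trigger belong to the case they
#' triggered — they are valid patient data.
#'
#' @param stream `data.frame` with at least columns `time` and `key`,
#'   time-sorted (as produced by [generate_stream()]).
#' @param config A [segmenter_config()].
#' @param end_time Clock time at which the stream ends; defaults to the last
#'   message time (an open case then closes with reason `"stream-end"`
#'   unless the timeout fired earlier).
#' @return A list with `boundaries` (list of `case_boundary`), `assignment`
#'   (integer per message: case number, or 0 for between-cases; `NA` when the
#'   message was deleted by `delete_between_cases`), and `residual` (row
#'   indices outside all cases).
#' @export
segment_stream <- function(stream, config = segmenter_config(),
                           end_time = NULL) {
  seg <- new_segmenter(config)
  boundaries <- list()
  collect <- function(evs) {
    for (ev in evs) {
      if (ev$type == "case-started") {
        boundaries[[length(boundaries) + 1L]] <<- ev$boundary
      } else {
        k <- length(boundaries)
        boundaries[[k]]$case_end <<- ev$boundary$case_end
        boundaries[[k]]$end_reason <<- ev$boundary$end_reason
      }
    }
  }
  n <- nrow(stream)
  for (i in seq_len(n)) collect(feed(seg, stream$time[i], stream$key[i]))
  if (is.null(end_time)) end_time <- if (n) stream$time[n] else -Inf
  collect(finalize_segmenter(seg, end_time))

  assignment <- integer(n)
  if (n && length(boundaries)) {
    win <- config$start_window_s
    starts <- vapply(boundaries, function(b)
      if (b$start_reason == "threshold-met") b$case_start - win else b$case_start,
      numeric(1))
    ends <- vapply(boundaries, function(b)
      if (is.na(b$case_end)) Inf else b$case_end, numeric(1))
    for (k in seq_along(boundaries)) {
      lo <- if (k > 1L) max(starts[k], ends[k - 1L]) else starts[k]
      # date-split cases end exactly at midnight; the midnight message belongs
      # to the reopened case, so that boundary is half-open
      hi_ok <- if (identical(boundaries[[k]]$end_reason, "date-split"))
        stream$time < ends[k] else stream$time <= ends[k]
      inside <- stream$time >= lo & hi_ok & assignment == 0L
      assignment[inside] <- k
    }
  }
  residual <- which(assignment == 0L)
  if (config$delete_between_cases) assignment[assignment == 0L] <- NA_integer_
  list(boundaries = boundaries, assignment = assignment, residual = residual)
}
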