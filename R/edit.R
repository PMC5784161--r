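# Editing utilities: combine fragmented case files, cut out intervals,
# remove tracks.

# Coalesce time-sorted blocks of one srate: two blocks are contiguous when
# the gap between the last sample of one and the first of the next does not
# exceed 1.5x the nominal sampling interval (the same threshold that starts
# a new block during acquisition).
coalesce_blocks <- function(blocks, srate, gap_factor = 1.5) {
  if (length(blocks) <= 1L) return(blocks)
  ord <- order(vapply(blocks, `[[`, numeric(1), "start"))
  blocks <- blocks[ord]
  out <- list(blocks[[1L]])
  for (b in blocks[-1L]) {
    last <- out[[length(out)]]
    gap <- b$start - block_end(last)
    if (gap > 0 && gap <= gap_factor / srate) {
      out[[length(out)]] <- wave_block(last$start, srate, c(last$counts, b$counts))
    } else {
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' Merge fragmented recordings into one case
#'
#' Fragments of one anaesthesia case (e.g. produced by electrocautery-induced
#' stream gaps) are seamlessly combined: tracks with identical keys are
#' unified with their blocks and samples time-sorted, and contiguous wave
#' blocks re-joined. On exact-timestamp duplicates of numeric samples or
#' events the earlier input's sample wins (fragments are chronological; the
#' first write is the original capture).
#'
#' @param recordings Non-empty list of `vital_recording` objects.
#' @return A `vital_recording` with `rec_start` = the minimum of the inputs'
#'   and metadata merged (earlier input wins on key collisions).
#' @export
merge_recordings <- function(recordings) {
  if (inherits(recordings, "vital_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("merge requires at least one recording")
  if (length(recordings) == 1L) return(recordings[[1L]])
  rec_start <- min(vapply(recordings, `[[`, numeric(1), "rec_start"))
  metadata <- character()
  for (r in recordings)
    metadata <- c(metadata, r$metadata[!names(r$metadata) %in% names(metadata)])

  all_keys <- unique(unlist(lapply(recordings, function(r) names(r$tracks))))
  tracks <- vector("list", length(all_keys))
  for (i in seq_along(all_keys)) {
    key <- all_keys[i]
    parts <- list()
    for (r in recordings) if (!is.null(r$tracks[[key]]))
      parts[[length(parts) + 1L]] <- r$tracks[[key]]
    ref <- parts[[1L]]
    for (p in parts[-1L]) {
      same <- identical(p$kind, ref$kind) && identical(p$unit, ref$unit) &&
        isTRUE(all.equal(p$gain, ref$gain)) && isTRUE(all.equal(p$offset, ref$offset)) &&
        (ref$kind != "wave" || isTRUE(all.equal(p$srate, ref$srate)))
      if (!same)
        stop("merge conflict on track '", key,
             "': unit/gain/offset/srate differ between fragments")
    }
    if (ref$kind == "wave") {
      blocks <- coalesce_blocks(unlist(lapply(parts, `[[`, "blocks"),
                                       recursive = FALSE), ref$srate)
      tracks[[i]] <- wave_track(ref$device, ref$name, ref$unit, ref$gain,
                                ref$offset, ref$digital_min, ref$digital_max,
                                ref$srate, blocks)
    } else if (ref$kind == "numeric") {
      df <- do.call(rbind, lapply(parts, `[[`, "samples"))
      ord <- order(round(df$time * 1000))     # stable: earlier fragment wins ties
      df <- df[ord, , drop = FALSE]
      df <- df[!duplicated(round(df$time * 1000)), , drop = FALSE]
      tracks[[i]] <- numeric_track(ref$device, ref$name, ref$unit, df)
    } else {
      df <- do.call(rbind, lapply(parts, `[[`, "events"))
      ord <- order(round(df$time * 1000))
      df <- df[ord, , drop = FALSE]
      df <- df[!duplicated(data.frame(round(df$time * 1000), df$text)), , drop = FALSE]
      tracks[[i]] <- event_track(ref$device, ref$name, df)
    }
  }
  vital_recording(tracks, rec_start = rec_start, metadata = metadata)
}

#' Trim a recording to a time interval
#'
#' Keeps samples with time in `[t0, t1)`. Wave blocks straddling a boundary
#' are cut at the nearest inside sample; `rec_start` becomes
#' `max(rec_start, t0)`. An empty result is allowed.
#'
#' @param recording A `vital_recording`.
#' @param t0,t1 Interval bounds in epoch seconds, `t0 < t1`.
#' @return The trimmed `vital_recording`.
#' @export
trim_recording <- function(recording, t0, t1) {
  if (!(t0 < t1)) stop("trim requires t0 < t1")
  new_start <- max(recording$rec_start, t0)
  tracks <- lapply(recording$tracks, function(tr) {
    if (tr$kind == "wave") {
      blocks <- list()
      for (b in tr$blocks) {
        n <- length(b$counts)
        times <- b$start + (seq_len(n) - 1L) / b$srate
        keep <- which(times >= t0 - 1e-9 & times < t1 - 1e-9)
        if (length(keep))
          blocks[[length(blocks) + 1L]] <-
            wave_block(times[keep[1L]], b$srate, b$counts[keep])
      }
      wave_track(tr$device, tr$name, tr$unit, tr$gain, tr$offset,
                 tr$digital_min, tr$digital_max, tr$srate, blocks)
    } else if (tr$kind == "numeric") {
      keep <- tr$samples$time >= t0 - 1e-9 & tr$samples$time < t1 - 1e-9
      numeric_track(tr$device, tr$name, tr$unit, tr$samples[keep, , drop = FALSE])
    } else {
      keep <- tr$events$time >= t0 - 1e-9 & tr$events$time < t1 - 1e-9
      event_track(tr$device, tr$name, tr$events[keep, , drop = FALSE])
    }
  })
  vital_recording(tracks, rec_start = new_start, metadata = recording$metadata)
}

#' Split a recording at a time point
#'
#' Convenience inverse of [merge_recordings()]: partitions a recording into
#' the parts before and from `t`. `merge_recordings(split_recording(R, t))`
#' reproduces `R` for any split point.
#'
#' @param recording A `vital_recording`.
#' @param t Split time (epoch seconds).
#' @return List of two `vital_recording` objects.
#' @export
split_recording <- function(recording, t) {
  list(trim_recording(recording, recording$rec_start, t),
       trim_recording(recording, t, Inf))
}

#' Remove tracks from a recording
#'
#' Reduces file size by dropping unnecessary data tracks. Unknown keys are
#' ignored with a warning; metadata and all other tracks are untouched.
#'
#' @param recording A `vital_recording`.
#' @param keys Character vector of `device/name` track keys to remove.
#' @return The reduced `vital_recording`.
#' @export
drop_tracks <- function(recording, keys) {
  unknown <- setdiff(keys, names(recording$tracks))
  if (length(unknown))
    warning("ignoring unknown track keys: ", paste(unknown, collapse = ", "))
  keep <- recording$tracks[!names(recording$tracks) %in% keys]
  vital_recording(keep, rec_start = recording$rec_start,
                  metadata = recording$metadata)
}
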