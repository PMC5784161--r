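# Container format (version 1), little-endian throughout, whole stream
# wrapped in a single gzip (RFC 1952) member:
#
#   magic "VITR" | version u8
#   rec_start f64 (epoch seconds)
#   n_meta u16, then n_meta x (key str, value str)      str = u16 length + UTF-8
#   n_tracks u16, then per track:
#     id u16 | device str | name str | kind u8 | unit str |
#     gain f64 | offset f64 | digital_min i32 | digital_max i32 | srate f64
#   packets until EOF:
#     track id u16 | packet type u8 | payload length u32 | payload
#       wave block payload:   start_ms u32 | n u32 | counts i16 x n
#       numeric batch payload: n u32 | times_ms u32 x n | values f32 x n
#       event batch payload:   n u32 | n x (t_ms u32 | text str)
#
# Sample times are stored as milliseconds since rec_start (exact for all
# catalog intervals, 1/500 s = 2 ms); counts as 16-bit signed integers;
# numeric values as 32-bit floats. The header is decodable without touching
# any payload, and payloads can be skipped via their length prefixes.

VITAL_MAGIC <- charToRaw("VITR")
VITAL_VERSION <- 1L

ms_of <- function(t, rec_start) {
  ms <- round((t - rec_start) * 1000)
  if (any(ms < 0)) stop("sample time precedes rec_start")
  as.integer(ms)
}

serialize_header <- function(rec, keys) {
  buf <- new_wbuf()
  wbuf_put(buf, VITAL_MAGIC)
  wbuf_put(buf, w_u8(VITAL_VERSION))
  wbuf_put(buf, w_f64(rec$rec_start))
  wbuf_put(buf, w_u16(length(rec$metadata)))
  for (k in names(rec$metadata)) {
    wbuf_put(buf, w_str(k))
    wbuf_put(buf, w_str(rec$metadata[[k]]))
  }
  wbuf_put(buf, w_u16(length(keys)))
  for (i in seq_along(keys)) {
    tr <- rec$tracks[[keys[i]]]
    is_wave <- tr$kind == "wave"
    wbuf_put(buf, c(w_u16(i), w_str(tr$device), w_str(tr$name),
                    w_u8(KIND_CODES[[tr$kind]]), w_str(tr$unit),
                    w_f64(tr$gain), w_f64(tr$offset),
                    w_i32(if (is_wave) tr$digital_min else 0L),
                    w_i32(if (is_wave) tr$digital_max else 0L),
                    w_f64(if (is_wave) tr$srate else 0)))
  }
  wbuf_raw(buf)
}

serialize_packets <- function(rec, keys) {
  buf <- new_wbuf()
  n_packets <- integer(length(keys))
  names(n_packets) <- keys
  for (i in seq_along(keys)) {
    tr <- rec$tracks[[keys[i]]]
    if (tr$kind == "wave") {
      for (b in tr$blocks) {
        payload <- c(w_i32(ms_of(b$start, rec$rec_start)),
                     w_i32(length(b$counts)), w_i16(b$counts))
        wbuf_put(buf, c(w_u16(i), w_u8(1L), w_i32(length(payload)), payload))
        n_packets[i] <- n_packets[i] + 1L
      }
    } else if (tr$kind == "numeric") {
      if (nrow(tr$samples)) {
        payload <- c(w_i32(nrow(tr$samples)),
                     w_i32(ms_of(tr$samples$time, rec$rec_start)),
                     w_f32(tr$samples$value))
        wbuf_put(buf, c(w_u16(i), w_u8(2L), w_i32(length(payload)), payload))
        n_packets[i] <- 1L
      }
    } else {
      if (nrow(tr$events)) {
        pb <- new_wbuf()
        wbuf_put(pb, w_i32(nrow(tr$events)))
        for (j in seq_len(nrow(tr$events))) {
          wbuf_put(pb, w_i32(ms_of(tr$events$time[j], rec$rec_start)))
          wbuf_put(pb, w_str(tr$events$text[j]))
        }
        payload <- wbuf_raw(pb)
        wbuf_put(buf, c(w_u16(i), w_u8(3L), w_i32(length(payload)), payload))
        n_packets[i] <- 1L
      }
    }
  }
  list(raw = wbuf_raw(buf), n_packets = n_packets)
}

#' Write a recording to a block-compressed container file
#'
#' The canonical writer sorts tracks by key and emits one packet per wave
#' block and one batch packet per non-empty numeric/event track, so that
#' decompress, parse and re-serialize is byte-stable. Writing is lossless:
#' counts are stored as-is, times to millisecond precision relative to
#' `rec_start`, numeric values as 32-bit floats.
#'
#' @param recording A valid `vital_recording`.
#' @param path Output file path.
#' @param compress Wrap the stream in gzip (the container's standard framing).
#'   `FALSE` writes the identical packet stream uncompressed, mainly useful
#'   for measuring the compression gain.
#' @return Invisibly, a list with `path`, `bytes` (on-disk size), and
#'   `n_packets` (named per-track packet counts emitted).
#' @export
write_vital <- function(recording, path, compress = TRUE) {
  validate_recording(recording)
  keys <- sort(names(recording$tracks), method = "radix")
  header <- serialize_header(recording, keys)
  body <- serialize_packets(recording, keys)
  con <- if (compress) gzfile(path, "wb", compression = 6L) else file(path, "wb")
  ok <- tryCatch({
    writeBin(header, con)
    writeBin(body$raw, con)
    TRUE
  }, error = function(e) {
    close(con)
    stop("cannot write container file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  close(con)
  invisible(list(path = path, bytes = file.size(path), n_packets = body$n_packets))
}

parse_header <- function(cur, path) {
  magic <- tryCatch(rcur_take(cur, 4L), error = function(e)
    stop("'", path, "' is not a vital container (file too short)", call. = FALSE))
  if (!identical(magic, VITAL_MAGIC))
    stop("'", path, "' is not a vital container (bad magic)", call. = FALSE)
  version <- r_u8(cur)
  if (version != VITAL_VERSION)
    stop("unsupported container format version ", version, call. = FALSE)
  rec_start <- r_f64(cur)
  n_meta <- r_u16(cur)
  metadata <- character(n_meta)
  keys <- character(n_meta)
  for (i in seq_len(n_meta)) {
    keys[i] <- r_str(cur)
    metadata[i] <- r_str(cur)
  }
  names(metadata) <- keys
  n_tracks <- r_u16(cur)
  dir <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    id <- r_u16(cur)
    device <- r_str(cur)
    name <- r_str(cur)
    kind_code <- r_u8(cur)
    kind <- names(KIND_CODES)[match(kind_code, KIND_CODES)]
    if (is.na(kind))
      stop("unknown track kind code ", kind_code, " in '", path, "'", call. = FALSE)
    unit <- r_str(cur)
    gain <- r_f64(cur); offset <- r_f64(cur)
    dmin <- r_i32(cur); dmax <- r_i32(cur); srate <- r_f64(cur)
    dir[[id]] <- list(id = id, device = device, name = name, kind = kind,
                      unit = unit, gain = gain, offset = offset,
                      digital_min = if (kind == "wave") dmin else NA_integer_,
                      digital_max = if (kind == "wave") dmax else NA_integer_,
                      srate = if (kind == "wave") srate else NA_real_)
  }
  list(rec_start = rec_start, metadata = metadata, dir = dir)
}

directory_df <- function(hdr, n_packets = NULL) {
  dir <- hdr$dir
  out <- data.frame(
    key = vapply(dir, function(d) track_key(d$device, d$name), character(1)),
    device = vapply(dir, `[[`, character(1), "device"),
    name = vapply(dir, `[[`, character(1), "name"),
    kind = vapply(dir, `[[`, character(1), "kind"),
    unit = vapply(dir, `[[`, character(1), "unit"),
    gain = vapply(dir, `[[`, numeric(1), "gain"),
    offset = vapply(dir, `[[`, numeric(1), "offset"),
    digital_min = vapply(dir, `[[`, integer(1), "digital_min"),
    digital_max = vapply(dir, `[[`, integer(1), "digital_max"),
    srate = vapply(dir, `[[`, numeric(1), "srate"),
    stringsAsFactors = FALSE)
  if (!is.null(n_packets)) out$n_packets <- n_packets
  out
}

# Shared packet walk. decode_ids: track ids whose payloads are decoded;
# others are skipped via the length prefix without interpreting a byte.
walk_packets <- function(cur, hdr, decode_ids) {
  n <- length(hdr$dir)
  n_packets <- integer(n)
  waves <- vector("list", n)       # list of wave blocks per track id
  numerics <- vector("list", n)    # list of data.frames
  events <- vector("list", n)
  decoded_bytes <- 0
  decoded_wave_bytes <- 0
  truncated <- FALSE
  repeat {
    if (rcur_left(cur) == 0L) break
    ok <- tryCatch({
      id <- r_u16(cur)
      ptype <- r_u8(cur)
      len <- r_i32(cur)
      if (id < 1L || id > n) stop("packet references unknown track id ", id)
      if (id %in% decode_ids) {
        start_pos <- cur$pos
        if (ptype == 1L) {
          start_ms <- r_i32(cur)
          nct <- r_i32(cur)
          counts <- r_i16(cur, nct)
          waves[[id]][[length(waves[[id]]) + 1L]] <-
            wave_block(hdr$rec_start + start_ms / 1000, hdr$dir[[id]]$srate, counts)
        } else if (ptype == 2L) {
          ns <- r_i32(cur)
          tms <- r_i32(cur, ns)
          vals <- r_f32(cur, ns)
          numerics[[id]][[length(numerics[[id]]) + 1L]] <-
            data.frame(time = hdr$rec_start + tms / 1000, value = vals)
        } else if (ptype == 3L) {
          ne <- r_i32(cur)
          tms <- integer(ne); txt <- character(ne)
          for (j in seq_len(ne)) { tms[j] <- r_i32(cur); txt[j] <- r_str(cur) }
          events[[id]][[length(events[[id]]) + 1L]] <-
            data.frame(time = hdr$rec_start + tms / 1000, text = txt,
                       stringsAsFactors = FALSE)
        } else stop("unknown packet type ", ptype)
        decoded_bytes <- decoded_bytes + (cur$pos - start_pos)
        if (ptype == 1L) decoded_wave_bytes <- decoded_wave_bytes + (cur$pos - start_pos)
      } else {
        rcur_skip(cur, len)
      }
      n_packets[id] <- n_packets[id] + 1L
      TRUE
    }, error = function(e) {
      if (grepl("short read", conditionMessage(e))) FALSE else stop(e)
    })
    if (!ok) { truncated <- TRUE; break }
  }
  list(n_packets = n_packets, waves = waves, numerics = numerics,
       events = events, decoded_bytes = decoded_bytes,
       decoded_wave_bytes = decoded_wave_bytes, truncated = truncated)
}

build_track <- function(d, walk) {
  if (d$kind == "wave") {
    wave_track(d$device, d$name, unit = d$unit, gain = d$gain, offset = d$offset,
               digital_min = d$digital_min, digital_max = d$digital_max,
               srate = d$srate, blocks = walk$waves[[d$id]] %||% list())
  } else if (d$kind == "numeric") {
    parts <- walk$numerics[[d$id]]
    samples <- if (length(parts)) do.call(rbind, parts)
               else data.frame(time = numeric(), value = numeric())
    numeric_track(d$device, d$name, unit = d$unit, samples = samples)
  } else {
    parts <- walk$events[[d$id]]
    ev <- if (length(parts)) do.call(rbind, parts)
          else data.frame(time = numeric(), text = character())
    event_track(d$device, d$name, events = ev)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a container file
#'
#' Exact inverse of [write_vital()]. A stream truncated mid-packet (e.g. a
#' recording interrupted by power loss) is recovered up to the last complete
#' packet: the partial recording is returned with attribute `truncated = TRUE`
#' and a warning reporting how many packets were recovered.
#'
#' @param path Container file path.
#' @param tracks Optional character vector of track keys to decode; payloads
#'   of other tracks are skipped via their length prefixes (the tracks still
#'   appear, empty, in the result). `NULL` decodes everything.
#' @param compressed Set `FALSE` to read a stream written with
#'   `write_vital(compress = FALSE)`.
#' @return A `vital_recording` with attributes `truncated` (logical),
#'   `n_packets` (per-track packet counts) and `payload_bytes_decoded`.
#' @export
read_vital <- function(path, tracks = NULL, compressed = TRUE) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  stream <- read_stream_raw(path, compressed = compressed)
  cur <- new_rcur(stream$raw)
  hdr <- parse_header(cur, path)
  all_keys <- vapply(hdr$dir, function(d) track_key(d$device, d$name), character(1))
  decode_ids <- if (is.null(tracks)) seq_along(hdr$dir) else which(all_keys %in% tracks)
  walk <- walk_packets(cur, hdr, decode_ids)
  trks <- lapply(hdr$dir, build_track, walk = walk)
  rec <- vital_recording(trks, rec_start = hdr$rec_start, metadata = hdr$metadata)
  truncated <- stream$truncated || walk$truncated
  if (truncated)
    warning(sprintf("'%s' is truncated; recovered %d complete packets", path,
                    sum(walk$n_packets)), call. = FALSE)
  attr(rec, "truncated") <- truncated
  attr(rec, "n_packets") <- stats::setNames(walk$n_packets, all_keys)
  attr(rec, "payload_bytes_decoded") <- walk$decoded_bytes
  attr(rec, "wave_payload_bytes_decoded") <- walk$decoded_wave_bytes
  rec
}

#' Scan a container file without decoding samples
#'
#' Header-only scan backing the `list`/`trks` utilities: returns the track
#' directory and per-track packet counts. Payloads are skipped via their
#' length prefixes, so no sample byte is ever decoded (see the
#' `payload_bytes_decoded` attribute, always 0).
#'
#' @param path Container file path.
#' @param compressed As in [read_vital()].
#' @return A `data.frame` with one row per track (key, kind, unit, conversion
#'   factors, srate, `n_packets`), attributes `rec_start`, `metadata`,
#'   `truncated`, `payload_bytes_decoded`.
#' @export
scan_tracks <- function(path, compressed = TRUE) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  stream <- read_stream_raw(path, compressed = compressed)
  cur <- new_rcur(stream$raw)
  hdr <- parse_header(cur, path)
  walk <- walk_packets(cur, hdr, integer(0))
  out <- directory_df(hdr, walk$n_packets)
  attr(out, "rec_start") <- hdr$rec_start
  attr(out, "metadata") <- hdr$metadata
  attr(out, "truncated") <- stream$truncated || walk$truncated
  attr(out, "payload_bytes_decoded") <- walk$decoded_bytes
  out
}
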