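# Plain EDF (European Data Format, 1992) export of wave tracks, with
# optional gridded numerics. One signal per track; 16-bit samples; the data
# record duration is the smallest d in {1, 2, 4, 8, 16} s making
# samples-per-record integral for every exported rate.

edf_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1L, width)
  formatC(s, width = -width, flag = "-")
}

edf_num <- function(x, width = 8L) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- substr(formatC(x, digits = width - 2L, format = "g"), 1L, width)
  edf_field(s, width)
}

pick_record_duration <- function(srates) {
  for (d in c(1, 2, 4, 8, 16)) {
    spr <- srates * d
    if (all(abs(spr - round(spr)) < 1e-9)) return(d)
  }
  stop("no data-record duration in {1,2,4,8,16} s gives an integral ",
       "samples-per-record for rates ", paste(srates, collapse = ", "),
       "; resample the offending track first")
}

edf_labels <- function(keys) {
  lab <- substr(keys, 1L, 16L)
  while (anyDuplicated(lab)) {
    d <- which(duplicated(lab) | duplicated(lab, fromLast = TRUE))
    for (grp in split(d, lab[d])) {
      for (j in seq_along(grp)) {
        suf <- paste0("~", j)
        lab[grp[j]] <- paste0(substr(keys[grp[j]], 1L, 16L - nchar(suf)), suf)
      }
    }
  }
  lab
}

#' Export a recording to an EDF file
#'
#' Writes every wave track (and, optionally, numeric tracks gridded at one
#' sample per data record with carry-forward) as one EDF signal. Physical
#' min/max come from the track's gain/offset applied to its digital range,
#' so raw counts pass through unchanged. Acquisition gaps are filled with the
#' track's physical minimum — never a mid-range value, so gaps stay visually
#' and numerically distinguishable — and listed in a sidecar gap log.
#' Patient/recording identification fields default to "X" (de-identified).
#'
#' @param recording A `vital_recording` with at least one wave track.
#' @param path Output file path.
#' @param include_numerics Also export numeric tracks (one sample per record,
#'   carry-forward, gaps at the observed minimum).
#' @param gap_log Path of the sidecar TSV listing gap-filled intervals;
#'   default `paste0(path, ".gaps.tsv")`. `NULL` disables the sidecar.
#' @return Invisibly, a list with `record_duration`, `n_records`,
#'   `samples_per_record` and `gaps` (the gap table).
#' @export
export_edf <- function(recording, path, include_numerics = FALSE,
                       gap_log = paste0(path, ".gaps.tsv")) {
  waves <- recording$tracks[vapply(recording$tracks, function(tr)
    tr$kind == "wave", logical(1))]
  if (length(waves) == 0L) stop("EDF export requires at least one wave track")
  nums <- if (include_numerics)
    recording$tracks[vapply(recording$tracks, function(tr)
      tr$kind == "numeric" && nrow(tr$samples) > 0L, logical(1))]
  else list()

  d <- pick_record_duration(vapply(waves, `[[`, numeric(1), "srate"))
  t0 <- recording$rec_start
  last <- max(vapply(c(waves, nums), function(tr) {
    lt <- track_last_time(tr)
    if (is.na(lt)) t0 else lt
  }, numeric(1)))
  # records cover [t0, t0 + n_rec * d); the final sample must fall inside
  n_rec <- as.integer(floor((last - t0) / d + 1e-9)) + 1L

  sig <- list()
  gaps <- data.frame(track = character(), t_start = numeric(), t_end = numeric())
  for (key in names(waves)) {
    tr <- waves[[key]]
    spr <- as.integer(round(tr$srate * d))
    n_total <- spr * n_rec
    fill <- tr$digital_min
    buf <- rep.int(fill, n_total)
    covered <- rep(FALSE, n_total)
    for (b in tr$blocks) {
      i0 <- as.integer(round((b$start - t0) * tr$srate))
      n <- length(b$counts)
      sel <- seq.int(i0 + 1L, length.out = n)
      keep <- sel >= 1L & sel <= n_total
      buf[sel[keep]] <- b$counts[keep]
      covered[sel[keep]] <- TRUE
    }
    if (any(!covered)) {
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(!r$values))
        gaps <- rbind(gaps, data.frame(
          track = key, t_start = t0 + (starts[j] - 1L) / tr$srate,
          t_end = t0 + ends[j] / tr$srate))
    }
    sig[[key]] <- list(buf = buf, spr = spr, unit = tr$unit,
                       pmin = tr$gain * tr$digital_min + tr$offset,
                       pmax = tr$gain * tr$digital_max + tr$offset,
                       dmin = tr$digital_min, dmax = tr$digital_max)
  }
  for (key in names(nums)) {
    tr <- nums[[key]]
    grid <- t0 + d * (seq_len(n_rec) - 1L)
    vals <- grid_sample(tr$samples, grid, staleness = Inf)
    rng <- range(tr$samples$value)
    if (rng[1L] == rng[2L]) rng[2L] <- rng[1L] + 1
    vals[is.na(vals)] <- rng[1L]
    gain <- (rng[2L] - rng[1L]) / 65535
    sig[[key]] <- list(buf = as.integer(round((vals - rng[1L]) / gain)) - 32768L,
                       spr = 1L, unit = tr$unit, pmin = rng[1L], pmax = rng[2L],
                       dmin = -32768L, dmax = 32767L)
  }

  ns <- length(sig)
  start_ct <- as.POSIXct(t0, origin = "1970-01-01", tz = "UTC")
  hdr <- paste0(
    edf_field("0", 8L), edf_field("X", 80L), edf_field("X", 80L),
    edf_field(format(start_ct, "%d.%m.%y"), 8L),
    edf_field(format(start_ct, "%H.%M.%S"), 8L),
    edf_field(256L * (ns + 1L), 8L), edf_field("", 44L),
    edf_field(n_rec, 8L), edf_num(d, 8L), edf_field(ns, 4L))
  labels <- edf_labels(names(sig))
  per <- function(f, w) paste(vapply(sig, function(s) edf_field(f(s), w),
                                     character(1)), collapse = "")
  hdr <- paste0(hdr,
    paste(vapply(labels, edf_field, character(1), width = 16L), collapse = ""),
    per(function(s) "", 80L),                 # transducer
    per(function(s) s$unit, 8L),
    paste(vapply(sig, function(s) edf_num(s$pmin), character(1)), collapse = ""),
    paste(vapply(sig, function(s) edf_num(s$pmax), character(1)), collapse = ""),
    per(function(s) s$dmin, 8L),
    per(function(s) s$dmax, 8L),
    per(function(s) "", 80L),                 # prefiltering
    per(function(s) s$spr, 8L),
    per(function(s) "", 32L))
  stopifnot(nchar(hdr) == 256L * (ns + 1L))

  # record-major interleaving: rbind the per-signal (spr x n_rec) matrices
  mats <- lapply(sig, function(s) matrix(s$buf, nrow = s$spr, ncol = n_rec))
  data_vec <- as.integer(do.call(rbind, mats))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(data_vec, con, size = 2L, endian = "little")

  if (!is.null(gap_log) && nrow(gaps) > 0L)
    utils::write.table(gaps, gap_log, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(list(record_duration = d, n_records = n_rec,
                 samples_per_record = vapply(sig, `[[`, integer(1), "spr"),
                 labels = stats::setNames(labels, names(sig)), gaps = gaps))
}

#' Read an EDF file as a recording
#'
#' Minimal plain-EDF reader: every signal becomes a wave track holding one
#' contiguous block of the stored 16-bit samples, with gain/offset derived
#' from the header's physical/digital ranges.
#'
#' @param path EDF file path.
#' @return A `vital_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8L)                                   # version
  rd(80L); rd(80L)
  startdate <- rd(8L); starttime <- rd(8L)
  rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  d <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16L); rdv(80L)
  units <- rdv(8L)
  pmin <- as.numeric(rdv(8L)); pmax <- as.numeric(rdv(8L))
  dmin <- as.integer(rdv(8L)); dmax <- as.integer(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L)); rdv(32L)
  t0 <- as.numeric(as.POSIXct(paste(startdate, starttime),
                              format = "%d.%m.%y %H.%M.%S", tz = "UTC"))
  if (is.na(t0)) t0 <- 0
  data <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                  signed = TRUE, endian = "little")
  offs <- cumsum(c(0L, spr))
  tracks <- vector("list", ns)
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    take <- unlist(lapply(seq_len(n_rec) - 1L, function(r)
      r * rec_len + offs[i] + seq_len(spr[i])))
    counts <- data[take]
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    offset <- pmin[i] - gain * dmin[i]
    key <- strsplit(labels[i], "/", fixed = TRUE)[[1L]]
    device <- if (length(key) >= 2L) key[1L] else "EDF"
    name <- if (length(key) >= 2L) paste(key[-1L], collapse = "/") else labels[i]
    tracks[[i]] <- wave_track(device, name, units[i], gain, offset,
                              dmin[i], dmax[i], srate = spr[i] / d,
                              blocks = list(wave_block(t0, spr[i] / d, counts)))
  }
  vital_recording(tracks, rec_start = t0)
}
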