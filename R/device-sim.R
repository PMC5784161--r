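# Synthetic anaesthesia-device stream generator: the test bed standing in
# for RS-232 hardware. Waveforms are template pulse trains with seeded
# beat-level jitter (RR interval, per-beat amplitude, respiratory
# modulation); the EEG is band-limited noise. Numeric parameters are slow
# drifting trends sampled at the catalog intervals. Everything is fully
# determined by the scenario seed.

# Evaluate expr under a temporary RNG state so simulator calls do not
# perturb the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
}

# Sum-of-Gaussians templates evaluated on a beat/breath phase in [0, 1).
ecg_phase <- function(phase) {
  g <- function(mu, sd, amp) amp * exp(-0.5 * ((phase - mu) / sd)^2)
  g(0.18, 0.025, 0.15) + g(0.37, 0.012, -0.12) + g(0.40, 0.013, 1.0) +
    g(0.435, 0.012, -0.25) + g(0.62, 0.040, 0.30)
}

pulse_phase <- function(phase) {
  # systolic upstroke + dicrotic bump, normalised to [0, 1]
  g <- function(mu, sd, amp) amp * exp(-0.5 * ((phase - mu) / sd)^2)
  v <- g(0.22, 0.10, 1.0) + g(0.55, 0.12, 0.32)
  v / 1.02
}

cvp_phase <- function(phase) {
  g <- function(mu, sd, amp) amp * exp(-0.5 * ((phase - mu) / sd)^2)
  g(0.10, 0.06, 1.0) + g(0.35, 0.05, 0.6) + g(0.65, 0.08, 0.8)
}

capno_phase <- function(phase) {
  # inspiration (phase < 0.35): baseline; expiration: fast rise to a gently
  # sloping alveolar plateau
  rise <- 1 - exp(-pmax(phase - 0.35, 0) * 18)
  fall <- exp(-pmax(phase - 0.97, 0) * 120)
  rise * fall * (1 + 0.05 * pmax(phase - 0.35, 0))
}

# Phase/index machinery for a jittered pulse train.
beat_train <- function(duration_s, rate_per_min, rr_jitter = 0.03,
                       amp_jitter = 0.03) {
  mean_ival <- 60 / rate_per_min
  n_beats <- ceiling(duration_s / mean_ival * 1.5) + 8L
  ival <- mean_ival * (1 + rr_jitter * stats::rnorm(n_beats))
  ival <- pmax(ival, 0.4 * mean_ival)
  starts <- c(0, cumsum(ival))
  list(starts = starts, ival = ival,
       amp = 1 + amp_jitter * stats::rnorm(n_beats))
}

train_eval <- function(t, train, template) {
  idx <- findInterval(t, train$starts)
  idx[idx < 1L] <- 1L
  idx[idx > length(train$ival)] <- length(train$ival)
  phase <- (t - train$starts[idx]) / train$ival[idx]
  template(pmin(pmax(phase, 0), 1)) * train$amp[idx]
}

#' Synthesise a waveform as ADC counts
#'
#' Deterministic (for a fixed seed) synthesis of physiological-looking
#' waveforms: ECG, plethysmogram, arterial/central-venous pressure and
#' capnogram are template pulse trains at the scenario heart/respiratory
#' rate with seeded beat-to-beat jitter and respiratory modulation; EEG is
#' band-limited (AR-filtered) noise. Physical values are mapped to integer
#' counts through [wave_conversion()] for the given digitiser.
#'
#' @param kind `"ecg"`, `"pleth"`, `"abp"`, `"cvp"`, `"capno"` or `"eeg"`.
#' @param duration_s Duration in seconds (> 0).
#' @param srate Sampling rate in Hz (> 0).
#' @param seed Integer seed; the same seed yields identical counts.
#' @param adc Digitiser description ([adc_spec()]), default 10-bit ±5 V.
#' @param hr_bpm,resp_rate,sbp,dbp,spo2 Vitals shaping the templates.
#' @return Integer vector of `round(duration_s * srate)` counts within the
#'   digitiser range.
#' @export
synth_wave <- function(kind, duration_s, srate, seed = 1L, adc = adc_spec(),
                       hr_bpm = 72, resp_rate = 12, sbp = 120, dbp = 70,
                       spo2 = 98) {
  if (duration_s <= 0 || srate <= 0) stop("duration_s and srate must be > 0")
  if (!kind %in% names(WAVE_PHYS)) stop("unknown waveform kind '", kind, "'")
  n <- round(duration_s * srate)
  t <- (seq_len(n) - 1L) / srate
  cv <- wave_conversion(kind, adc)
  phys <- with_seed(seed, {
    resp <- sin(2 * pi * resp_rate / 60 * t + stats::runif(1, 0, 2 * pi))
    switch(kind,
      ecg = {
        tr <- beat_train(duration_s, hr_bpm)
        1.1 * train_eval(t, tr, ecg_phase) + 0.08 * resp
      },
      pleth = {
        tr <- beat_train(duration_s, hr_bpm)
        28 + 38 * train_eval(t, tr, pulse_phase) * (1 + 0.04 * resp)
      },
      abp = {
        tr <- beat_train(duration_s, hr_bpm)
        drift <- 1 + 0.04 * sin(2 * pi * t / 300 + stats::runif(1, 0, 2 * pi))
        (dbp + (sbp - dbp) * train_eval(t, tr, pulse_phase)) * drift +
          2.5 * resp
      },
      cvp = {
        tr <- beat_train(duration_s, hr_bpm)
        6 + 5 * train_eval(t, tr, cvp_phase) + 1.5 * resp
      },
      capno = {
        tr <- beat_train(duration_s, resp_rate, rr_jitter = 0.05,
                         amp_jitter = 0.02)
        38 * train_eval(t, tr, capno_phase)
      },
      eeg = {
        # AR(2) resonance near 10 Hz relative to srate, scaled to ~15 uV RMS
        r <- 0.95
        a1 <- 2 * r * cos(2 * pi * 10 / srate)
        a2 <- -r^2
        x <- stats::filter(stats::rnorm(n), c(a1, a2), method = "recursive")
        as.numeric(x) / stats::sd(x) * 15
      })
  })
  phys <- pmin(pmax(phys, cv$lo), cv$hi)
  cnt <- as.integer(round((phys - cv$offset) / cv$gain))
  pmin(pmax(cnt, adc$digital_min), adc$digital_max)
}

# Slow numeric trend at the catalog interval: baseline + seeded sinusoidal
# drift + small measurement noise, clipped to the plausible range and
# rounded to device precision (1 decimal).
synth_numeric <- function(times_rel, lo, hi, base, trend, seed) {
  with_seed(seed, {
    if (identical(trend, "ramp")) {
      v <- lo + base * times_rel / 3600
    } else {
      span <- hi - lo
      period <- stats::runif(1, 300, 900)
      v <- base + 0.02 * span * sin(2 * pi * times_rel / period +
                                    stats::runif(1, 0, 2 * pi)) +
        0.004 * span * stats::rnorm(length(times_rel))
    }
    round(pmin(pmax(v, lo), hi), 1)
  })
}

#' Define a simulation scenario
#'
#' A scenario fixes everything the generator needs: duration, seed, device
#' roster, per-device gap schedule (emulating electrocautery-style stream
#' interruptions) and the patient's vitals trajectory parameters.
#'
#' @param duration_s Scenario length in seconds.
#' @param seed Integer seed; fully determines the generated stream.
#' @param rec_start Recording start, epoch seconds (default
#'   2016-06-15 09:30:00 UTC).
#' @param roster Track roster (see [default_roster()]).
#' @param gaps `data.frame` with columns `device`, `t_start`, `t_end`
#'   (seconds relative to scenario start; `device = "*"` hits all devices),
#'   or `NULL` for a gap-free scenario.
#' @param hr_bpm,resp_rate,sbp,dbp,spo2 Baseline vitals.
#' @param events Include a small set of anaesthesia-event annotations.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(duration_s = 3600, seed = 1L,
                         rec_start = 1465983000,
                         roster = default_roster(), gaps = NULL,
                         hr_bpm = 72, resp_rate = 12, sbp = 120, dbp = 70,
                         spo2 = 98, events = TRUE) {
  if (!is.null(gaps)) {
    stopifnot(all(c("device", "t_start", "t_end") %in% names(gaps)))
    if (any(gaps$t_start < 0 | gaps$t_end > duration_s | gaps$t_start >= gaps$t_end))
      stop("gap intervals must lie within [0, duration_s] with t_start < t_end")
  }
  structure(list(duration_s = duration_s, seed = as.integer(seed),
                 rec_start = rec_start, roster = roster, gaps = gaps,
                 hr_bpm = hr_bpm, resp_rate = resp_rate, sbp = sbp, dbp = dbp,
                 spo2 = spo2, events = events),
            class = "sim_scenario")
}

#' Generate a time-sorted device message stream
#'
#' Numeric parameters emit one message per catalog interval starting at the
#' scenario start; waveforms are chunked into 1-second sample-block messages
#' to mimic streaming acquisition; a few event annotations are added. The
#' scenario's gap schedule is applied with [inject_gaps()]. The stream is
#' byte-identical across runs with the same scenario.
#'
#' @param scenario A [sim_scenario()].
#' @return A `data.frame` with columns `time` (epoch seconds), `device`,
#'   `param`, `key`, `kind`, `value` (numeric messages), `counts` (list
#'   column of integer chunks for waves), `text` (events), `srate`; sorted by
#'   time. Attributes `roster`, `rec_start`, `scenario`.
#' @export
generate_stream <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ro <- scenario$roster
  t0 <- scenario$rec_start
  dur <- scenario$duration_s
  parts <- vector("list", nrow(ro) + 1L)
  for (i in seq_len(nrow(ro))) {
    r <- ro[i, ]
    sd_i <- derive_seed(scenario$seed, i)
    if (r$kind == "wave") {
      counts <- synth_wave(r$wave_kind, dur, r$srate, seed = sd_i,
                           hr_bpm = scenario$hr_bpm,
                           resp_rate = scenario$resp_rate,
                           sbp = scenario$sbp, dbp = scenario$dbp,
                           spo2 = scenario$spo2)
      idx0 <- seq_along(counts) - 1L
      chunk_id <- floor(idx0 / r$srate)   # 1 s chunks; uneven at non-integer rates
      chunks <- split(counts, chunk_id)
      starts_rel <- idx0[!duplicated(chunk_id)] / r$srate
      parts[[i]] <- data.frame(time = t0 + starts_rel,
                               device = r$device, param = r$param,
                               key = track_key(r$device, r$param),
                               kind = "wave", value = NA_real_,
                               text = NA_character_, srate = r$srate,
                               stringsAsFactors = FALSE)
      parts[[i]]$counts <- unname(chunks)
    } else {
      times_rel <- seq(0, by = r$interval_s, length.out = floor(dur / r$interval_s))
      base <- r$base
      if (r$param == "HR" || r$param == "PR") base <- scenario$hr_bpm
      if (r$param == "SPO2") base <- scenario$spo2
      vals <- synth_numeric(times_rel, r$lo, r$hi, base, r$trend, sd_i)
      parts[[i]] <- data.frame(time = t0 + times_rel,
                               device = r$device, param = r$param,
                               key = track_key(r$device, r$param),
                               kind = "numeric", value = vals,
                               text = NA_character_, srate = NA_real_,
                               stringsAsFactors = FALSE)
      parts[[i]]$counts <- rep(list(NULL), length(times_rel))
    }
  }
  if (isTRUE(scenario$events)) {
    ev_rel <- unique(pmin(c(30, round(dur * 0.25), round(dur * 0.6)), dur - 1))
    ev <- data.frame(time = t0 + ev_rel, device = "EVENT", param = "EVENT",
                     key = "EVENT/EVENT", kind = "event", value = NA_real_,
                     text = c("Induction", "Incision", "Note")[seq_along(ev_rel)],
                     srate = NA_real_, stringsAsFactors = FALSE)
    ev$counts <- rep(list(NULL), nrow(ev))
    parts[[nrow(ro) + 1L]] <- ev
  }
  stream <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  ord <- order(stream$time, stream$device, stream$param, method = "radix")
  stream <- stream[ord, , drop = FALSE]
  rownames(stream) <- NULL
  if (!is.null(scenario$gaps)) {
    gaps <- scenario$gaps
    gaps$t_start <- gaps$t_start + t0
    gaps$t_end <- gaps$t_end + t0
    stream <- inject_gaps(stream, gaps)
  }
  attr(stream, "roster") <- ro
  attr(stream, "rec_start") <- t0
  attr(stream, "scenario") <- scenario
  stream
}

#' Remove messages falling into scheduled gaps
#'
#' Emulates electrocautery-style stream interruptions: messages whose
#' timestamps fall inside any `[t_start, t_end)` interval of the schedule are
#' dropped; everything else is untouched and order is preserved.
#'
#' @param stream A message stream (see [generate_stream()]).
#' @param schedule `data.frame` with columns `device` (`"*"` = all devices),
#'   `t_start`, `t_end` in the stream's time base; intervals sorted and
#'   disjoint per device.
#' @return The filtered stream.
#' @export
inject_gaps <- function(stream, schedule) {
  if (is.null(schedule) || nrow(schedule) == 0L) return(stream)
  drop <- rep(FALSE, nrow(stream))
  for (j in seq_len(nrow(schedule))) {
    hit <- stream$time >= schedule$t_start[j] & stream$time < schedule$t_end[j]
    if (!identical(schedule$device[j], "*"))
      hit <- hit & stream$device == schedule$device[j]
    drop <- drop | hit
  }
  out <- stream[!drop, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("roster", "rec_start", "scenario"))
    attr(out, a) <- attr(stream, a)
  out
}

#' Assemble a message stream into a recording
#'
#' Concatenates wave chunk messages into contiguous sample blocks — a new
#' block starts whenever the inter-sample spacing exceeds `gap_factor` times
#' the nominal interval, which isolates true acquisition gaps while
#' tolerating timing jitter — and collects numeric and event messages into
#' their tracks.
#'
#' @param stream A stream from [generate_stream()] (or a compatible
#'   `data.frame` carrying `roster` and `rec_start` attributes).
#' @param roster,rec_start Overrides for the stream attributes.
#' @param metadata Metadata for the resulting recording.
#' @param gap_factor Block-splitting threshold (default 1.5).
#' @return A `vital_recording`.
#' @export
stream_to_recording <- function(stream, roster = attr(stream, "roster"),
                                rec_start = attr(stream, "rec_start"),
                                metadata = NULL, gap_factor = 1.5) {
  if (is.null(roster) || is.null(rec_start))
    stop("stream must carry roster/rec_start attributes or they must be given")
  if (is.null(metadata)) {
    metadata <- c(format_version = "1",
                  devices = paste(sort(unique(roster$device)), collapse = ","))
  }
  tracks <- list()
  for (i in seq_len(nrow(roster))) {
    r <- roster[i, ]
    rows <- which(stream$key == track_key(r$device, r$param))
    if (r$kind == "wave") {
      cv <- wave_conversion(r$wave_kind)
      blocks <- list()
      if (length(rows)) {
        starts <- stream$time[rows]
        chunks <- stream$counts[rows]
        lens <- lengths(chunks)
        ends <- starts + (lens - 1L) / r$srate
        spacing <- starts[-1L] - ends[-length(ends)]
        grp <- cumsum(c(0L, as.integer(spacing > gap_factor / r$srate + 1e-12)))
        for (g in unique(grp)) {
          sel <- grp == g
          blocks[[length(blocks) + 1L]] <-
            wave_block(starts[sel][1L], r$srate,
                       unlist(chunks[sel], use.names = FALSE))
        }
      }
      tracks[[length(tracks) + 1L]] <-
        wave_track(r$device, r$param, cv$unit, cv$gain, cv$offset,
                   0L, 1023L, r$srate, blocks)
    } else {
      tracks[[length(tracks) + 1L]] <-
        numeric_track(r$device, r$param, r$unit,
                      data.frame(time = stream$time[rows],
                                 value = stream$value[rows]))
    }
  }
  ev_rows <- which(stream$kind == "event")
  if (length(ev_rows)) {
    tracks[[length(tracks) + 1L]] <-
      event_track("EVENT", "EVENT",
                  data.frame(time = stream$time[ev_rows],
                             text = stream$text[ev_rows],
                             stringsAsFactors = FALSE))
  }
  vital_recording(tracks, rec_start = rec_start, metadata = metadata)
}

#' Generate a full recording from a scenario
#'
#' Convenience wrapper: [generate_stream()] then [stream_to_recording()].
#'
#' @param scenario A [sim_scenario()].
#' @return A `vital_recording`.
#' @export
simulate_recording <- function(scenario) {
  stream_to_recording(generate_stream(scenario))
}
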