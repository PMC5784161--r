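# Shared fixtures, built in code. Times live on the millisecond grid the
# container stores, so round trips are exact; numeric values are float32
# representable where exactness matters.

T0 <- 1465983000  # 2016-06-15 09:30:00 UTC

make_numeric <- function(device = "Solar8000", name = "HR", times, values,
                         unit = "/min") {
  numeric_track(device, name, unit, data.frame(time = times, value = values))
}

make_wave <- function(device = "TramRac4A", name = "ECG_II", srate = 100,
                      start = T0, counts = 0:999, gain = 10 / 1023,
                      offset = -5) {
  wave_track(device, name, "mV", gain, offset, 0L, 1023L, srate,
             list(wave_block(start, srate, counts)))
}

# Small but complete recording: one wave, two numerics, one event track.
small_recording <- function() {
  vital_recording(list(
    make_wave(counts = rep_len(0:1023, 1000)),
    make_numeric(times = T0 + seq(0, 58, by = 2), values = round(70 + sin(1:30), 1)),
    make_numeric(name = "SPO2", unit = "%", times = T0 + seq(0, 58, by = 2),
                 values = rep(c(98, 97.5), 15)),
    event_track("EVENT", "EVENT",
                data.frame(time = T0 + c(5, 30), text = c("Induction", "Incision")))),
    rec_start = T0,
    metadata = c(format_version = "1", devices = "Solar8000,TramRac4A",
                 operator = "or-3 laptop"))
}

# Randomised recording on the ms grid, for property tests.
random_recording <- function(seed) {
  set.seed(seed)
  n_num <- sample(1:3, 1)
  tracks <- list()
  for (i in seq_len(n_num)) {
    times <- T0 + sort(sample(seq(0, 600, by = 0.5), sample(5:60, 1)))
    vals <- round(runif(length(times), 40, 180), 2)
    tracks[[length(tracks) + 1L]] <- make_numeric(name = paste0("N", i),
                                                  times = times, values = vals)
  }
  for (i in seq_len(sample(1:2, 1))) {
    srate <- sample(c(100, 125, 250, 500), 1)
    blocks <- list()
    t <- T0 + sample(0:10, 1)
    for (b in seq_len(sample(1:3, 1))) {
      n <- sample(50:400, 1)
      blocks[[b]] <- wave_block(t, srate, sample(0:1023, n, replace = TRUE))
      t <- t + n / srate + sample(2:20, 1)   # clear gap between blocks
    }
    tracks[[length(tracks) + 1L]] <- wave_track("W", paste0("WV", i), "mV",
                                                10 / 1023, -5, 0L, 1023L,
                                                srate, blocks)
  }
  vital_recording(tracks, rec_start = T0, metadata = c(format_version = "1"))
}

# Equality of recordings up to float32 numeric-value storage.
expect_recording_equal <- function(a, b, value_tol = 1e-6) {
  expect_equal(a$rec_start, b$rec_start)
  expect_setequal(names(a$tracks), names(b$tracks))
  expect_length(b$metadata, length(a$metadata))
  if (length(a$metadata))
    expect_equal(a$metadata[order(names(a$metadata))],
                 b$metadata[order(names(b$metadata))])
  for (k in names(a$tracks)) {
    ta <- a$tracks[[k]]; tb <- b$tracks[[k]]
    expect_equal(ta$kind, tb$kind, info = k)
    expect_equal(ta$unit, tb$unit, info = k)
    expect_equal(ta$gain, tb$gain, info = k)
    expect_equal(ta$offset, tb$offset, info = k)
    if (ta$kind == "wave") {
      expect_equal(length(ta$blocks), length(tb$blocks), info = k)
      for (j in seq_along(ta$blocks)) {
        expect_identical(ta$blocks[[j]]$counts, tb$blocks[[j]]$counts, info = k)
        expect_equal(ta$blocks[[j]]$start, tb$blocks[[j]]$start,
                     tolerance = 1e-9, info = k)
      }
    } else if (ta$kind == "numeric") {
      expect_equal(ta$samples$time, tb$samples$time, tolerance = 1e-9, info = k)
      expect_equal(ta$samples$value, tb$samples$value,
                   tolerance = value_tol, info = k)
    } else {
      expect_equal(ta$events, tb$events, info = k)
    }
  }
}

# Message stream with HR/SpO2 at given relative times (both signals).
hr_spo2_stream <- function(rel_times, t0 = T0) {
  df <- rbind(
    data.frame(time = t0 + rel_times, key = "Solar8000/HR", value = 70),
    data.frame(time = t0 + rel_times, key = "Solar8000/SPO2", value = 98))
  df[order(df$time, df$key), , drop = FALSE]
}

# Brute-force window-counting oracle: earliest message time at which both
# signals have arrived more than `thr` times within the trailing window.
oracle_case_start <- function(stream, window = 60, thr = 5) {
  hr <- stream$time[grepl("/HR$", stream$key)]
  sp <- stream$time[grepl("/SPO2$", stream$key)]
  for (t in sort(unique(stream$time))) {
    if (sum(hr > t - window & hr <= t) > thr &&
        sum(sp > t - window & sp <= t) > thr) return(t)
  }
  NA_real_
}

# Brute-force centered-window median oracle.
oracle_rolling_median <- function(samples, window_s) {
  vapply(seq_len(nrow(samples)), function(i) {
    sel <- abs(samples$time - samples$time[i]) <= window_s / 2 + 1e-9
    stats::median(samples$value[sel])
  }, numeric(1))
}
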