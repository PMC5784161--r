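test_that("synth_wave produces the exact sample counts for catalog rates", {
  eeg <- synth_wave("eeg", 60, 128, seed = 1)
  expect_length(eeg, 7680L)
  capno <- synth_wave("capno", 16, 62.5, seed = 1)
  expect_length(capno, 1000L)
  expect_error(synth_wave("emg", 10, 100), "unknown waveform kind")
  expect_error(synth_wave("ecg", 0, 100), "must be > 0")
})

test_that("synth_wave is seed-deterministic and respects the digitiser range", {
  for (kind in c("ecg", "pleth", "abp", "cvp", "capno", "eeg")) {
    a <- synth_wave(kind, 10, 125, seed = 99)
    b <- synth_wave(kind, 10, 125, seed = 99)
    expect_identical(a, b, info = kind)
    expect_true(all(a >= 0L & a <= 1023L), info = kind)
    c2 <- synth_wave(kind, 10, 125, seed = 100)
    expect_false(identical(a, c2), info = kind)
  }
})

test_that("numeric messages arrive at the catalog interval", {
  sc <- sim_scenario(duration_s = 60, seed = 2)
  st <- generate_stream(sc)
  hr <- st[st$key == "Solar8000/HR", ]
  expect_equal(nrow(hr), 30L)                       # every 2 s over 60 s
  expect_equal(unique(diff(hr$time)), 2)
  orch <- st[st$key == "OrchestraA/RATE", ]
  expect_equal(nrow(orch), 60L)                     # every 1 s
  primus <- st[st$device == "Primus" & st$param == "MAC", ]
  expect_equal(unique(diff(primus$time)), 7)
})

test_that("generate_stream is byte-identical for a fixed scenario", {
  sc <- sim_scenario(duration_s = 30, seed = 4)
  s1 <- generate_stream(sc)
  s2 <- generate_stream(sc)
  attributes(s1) <- attributes(s1)[c("names", "row.names", "class")]
  attributes(s2) <- attributes(s2)[c("names", "row.names", "class")]
  expect_identical(s1, s2)
})

test_that("scheduled gaps silence a device and only that device", {
  gaps <- data.frame(device = "Solar8000", t_start = 100, t_end = 160)
  sc <- sim_scenario(duration_s = 300, seed = 6, gaps = gaps)
  st <- generate_stream(sc)
  rel <- st$time - sc$rec_start
  in_gap <- rel >= 100 & rel < 160
  expect_false(any(st$device == "Solar8000" & in_gap))
  expect_true(any(st$device == "BISVista" & in_gap))
  expect_error(sim_scenario(duration_s = 50,
                            gaps = data.frame(device = "*", t_start = 40,
                                              t_end = 60)),
               "within")
})

test_that("inject_gaps drops exactly the scheduled messages", {
  st <- data.frame(time = 0:59, device = "D", key = "D/X")
  expect_identical(inject_gaps(st, NULL), st)
  gone <- inject_gaps(st, data.frame(device = "*", t_start = 0, t_end = 60))
  expect_equal(nrow(gone), 0L)
  part <- inject_gaps(st, data.frame(device = "*", t_start = 10, t_end = 20))
  expect_equal(nrow(part), 50L)
})

test_that("gaps split wave tracks into blocks at the acquisition boundary", {
  gaps <- data.frame(device = "TramRac4A", t_start = 20, t_end = 30)
  rec <- stream_to_recording(generate_stream(
    sim_scenario(duration_s = 60, seed = 8, gaps = gaps, events = FALSE)))
  ecg <- rec$tracks[["TramRac4A/ECG_II"]]
  expect_length(ecg$blocks, 2L)
  expect_equal(track_stats(ecg)$n, 50L * 500L)      # 10 s removed
  expect_equal(track_stats(ecg)$rate, 500)          # gap excluded from coverage
})

test_that("emulated rates measure back at the catalog values over one minute", {
  sc <- sim_scenario(duration_s = 60, seed = 1,
                     roster = default_roster(include_capno_wave = TRUE))
  rec <- stream_to_recording(generate_stream(sc))
  expect_equal(track_stats(rec$tracks[["BISVista/EEG1"]])$n, 7680L)
  expect_equal(track_stats(rec$tracks[["TramRac4A/ECG_II"]])$n, 30000L)
  expect_equal(track_stats(rec$tracks[["TramRac4A/PLETH"]])$n, 30000L)
  expect_equal(track_stats(rec$tracks[["Primus/CO2"]])$n, 3750L)
  expect_equal(track_stats(rec$tracks[["Solar8000/HR"]])$n, 30L)
  expect_equal(track_stats(rec$tracks[["BISVista/EEG1"]])$rate, 128)
  expect_equal(track_stats(rec$tracks[["TramRac4A/ECG_II"]])$rate, 500)
  expect_equal(track_stats(rec$tracks[["Primus/CO2"]])$rate, 62.5)
})

test_that("the default roster carries the standard simultaneous-recording mix", {
  ro <- default_roster()
  waves <- ro[ro$kind == "wave", ]
  expect_equal(sum(waves$srate == 500), 7L)
  expect_equal(sum(waves$srate == 128), 2L)
  expect_equal(sum(ro$kind == "numeric"), 90L)
})

test_that("a default 10-minute scenario segments into exactly one case", {
  st <- generate_stream(sim_scenario(duration_s = 600, seed = 12))
  s <- segment_stream(st)
  expect_length(s$boundaries, 1L)
  expect_equal(s$boundaries[[1]]$case_start, attr(st, "rec_start") + 10)
})
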