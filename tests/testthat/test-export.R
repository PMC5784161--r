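test_that("carry-forward fills a 1 s grid from 2 s samples in pairs", {
  rec <- vital_recording(list(make_numeric(times = T0 + seq(0, 10, by = 2),
                                           values = c(70, 71, 72, 73, 74, 75))),
                         rec_start = T0)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_table(rec, path,
                     export_options(interval_s = 1,
                                    missing_policy = "carry-forward",
                                    max_staleness_s = 2))
  expect_false(anyNA(df[["Solar8000/HR"]]))
  expect_equal(df[["Solar8000/HR"]],
               c(70, 70, 71, 71, 72, 72, 73, 73, 74, 74, 75))
  # carry-forward never uses a sample older than the staleness limit
  for (i in seq_len(nrow(df))) {
    v <- df[["Solar8000/HR"]][i]
    src <- rec$tracks[[1]]$samples
    age <- df$time[i] - max(src$time[src$value == v] - T0)
    expect_lte(age, 2)
  }
})

test_that("zero staleness on an offset grid leaves every cell blank", {
  rec <- vital_recording(list(make_numeric(times = T0 + c(0.5, 2.5, 4.5),
                                           values = c(70, 71, 72))),
                         rec_start = T0)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_table(rec, path, export_options(interval_s = 1))
  expect_true(all(is.na(df[["Solar8000/HR"]])))
})

test_that("the native grid passes values through unchanged", {
  vals <- c(70, 71.5, 72, 68, 75, 74)
  rec <- vital_recording(list(make_numeric(times = T0 + seq(0, 10, by = 2),
                                           values = vals)), rec_start = T0)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_table(rec, path, export_options(interval_s = 2))
  expect_equal(df[["Solar8000/HR"]], vals)
  expect_warning(export_table(vital_recording(list(make_wave())), path),
                 "no numeric tracks")
})

test_that("import_table builds one track per column and skips bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,hr,spo2",
               paste(0:9, 70:79, c(98, "NA", rep(97, 8)), sep = ",")), path)
  rec <- import_table(path)
  expect_length(rec$tracks, 2L)
  expect_equal(nrow(rec$tracks[["CSV/hr"]]$samples), 10L)
  expect_equal(nrow(rec$tracks[["CSV/spo2"]]$samples), 9L)
  expect_equal(attr(rec, "n_skipped"), 1L)
  expect_equal(attr(rec, "time_mode"), "relative")
  expect_error(import_table(path, time_column = "clock"), "no time column")
})

test_that("table export then import recovers the numeric samples", {
  rec <- vital_recording(list(
    make_numeric(times = T0 + seq(0, 20, by = 2), values = round(runif(11, 60, 90), 2)),
    make_numeric(name = "SPO2", times = T0 + seq(0, 20, by = 2),
                 values = round(runif(11, 90, 100), 1))), rec_start = T0)
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(rec, path, export_options(interval_s = 2))
  back <- import_table(path)
  for (k in names(rec$tracks)) {
    expect_equal(back$tracks[[k]]$samples$value, rec$tracks[[k]]$samples$value)
    expect_equal(diff(back$tracks[[k]]$samples$time),
                 diff(rec$tracks[[k]]$samples$time))
  }
  # ISO time format round trips absolute times
  export_table(rec, path, export_options(interval_s = 2, time_format = "iso"))
  abs_back <- import_table(path)
  expect_equal(attr(abs_back, "time_mode"), "absolute")
  expect_equal(abs_back$tracks[["Solar8000/HR"]]$samples$time,
               rec$tracks[["Solar8000/HR"]]$samples$time)
})

test_that("EDF record duration is the smallest d with integral samples", {
  capno <- vital_recording(list(
    wave_track("Primus", "CO2", "mmHg", 80 / 1023, 0, 0L, 1023L, 62.5,
               list(wave_block(T0, 62.5, synth_wave("capno", 20, 62.5, 1))))),
    rec_start = T0)
  path <- withr::local_tempfile(fileext = ".edf")
  info <- export_edf(capno, path)
  expect_equal(info$record_duration, 2)
  expect_equal(unname(info$samples_per_record), 125L)

  both <- vital_recording(list(
    make_wave(srate = 500, counts = synth_wave("ecg", 10, 500, 1)),
    wave_track("BISVista", "EEG1", "uV", 500 / 1023, -250, 0L, 1023L, 128,
               list(wave_block(T0, 128, synth_wave("eeg", 10, 128, 1))))),
    rec_start = T0)
  info2 <- export_edf(both, withr::local_tempfile(fileext = ".edf"))
  expect_equal(info2$record_duration, 1)
  expect_equal(sort(unname(info2$samples_per_record)), c(128L, 500L))

  odd <- vital_recording(list(make_wave(srate = 3.3, counts = 1:33)),
                         rec_start = T0)
  expect_error(export_edf(odd, withr::local_tempfile()), "resample")
  expect_error(export_edf(vital_recording(), withr::local_tempfile()),
               "at least one wave track")
})

test_that("EDF export round trips counts and physical values", {
  rec <- vital_recording(list(
    make_wave(srate = 100, counts = synth_wave("ecg", 8, 100, seed = 3))),
    rec_start = T0)
  path <- withr::local_tempfile(fileext = ".edf")
  export_edf(rec, path)
  back <- read_edf(path)
  orig <- rec$tracks[[1]]$blocks[[1]]$counts
  got <- back$tracks[[1]]$blocks[[1]]$counts[seq_along(orig)]
  expect_lte(max(abs(got - orig)), 1L)
  # physical values within one quantisation step
  pv_orig <- to_physical(orig, rec$tracks[[1]])
  pv_back <- to_physical(got, back$tracks[[1]])
  expect_lt(max(abs(pv_back - pv_orig)), rec$tracks[[1]]$gain * 1.0001)
  # EDF start time preserved to the second
  expect_equal(back$rec_start, T0)
})

test_that("EDF header fields are laid out per the 1992 format", {
  rec <- vital_recording(list(make_wave(counts = rep(512L, 500), srate = 100)),
                         rec_start = T0)
  path <- withr::local_tempfile(fileext = ".edf")
  export_edf(rec, path)
  hdr <- readBin(path, "raw", 256)
  txt <- rawToChar(hdr)
  expect_equal(substr(txt, 1, 8), "0       ")
  expect_equal(trimws(substr(txt, 9, 88)), "X")          # de-identified patient
  expect_equal(substr(txt, 169, 176), "15.06.16")        # dd.mm.yy
  expect_equal(substr(txt, 177, 184), "09.30.00")        # hh.mm.ss
  expect_equal(as.integer(substr(txt, 185, 192)), 512L)  # header bytes, ns=1
  expect_equal(as.integer(substr(txt, 253, 256)), 1L)    # ns
  expect_equal(file.size(path), 512 + 5 * 100 * 2)       # 5 records x 100 spr
})

test_that("gaps are filled with the physical minimum and logged", {
  tr <- wave_track("D", "W", "mmHg", 350 / 1023, -50, 0L, 1023L, 100,
                   list(wave_block(T0, 100, rep(500L, 200)),
                        wave_block(T0 + 4, 100, rep(500L, 100))))
  rec <- vital_recording(list(tr), rec_start = T0)
  path <- withr::local_tempfile(fileext = ".edf")
  info <- export_edf(rec, path)
  expect_equal(nrow(info$gaps), 1L)
  expect_equal(info$gaps$t_start, T0 + 2)
  expect_equal(info$gaps$t_end, T0 + 4)
  expect_true(file.exists(paste0(path, ".gaps.tsv")))
  back <- read_edf(path)
  counts <- back$tracks[[1]]$blocks[[1]]$counts
  expect_true(all(counts[201:400] == 0L))   # digital minimum inside the gap
})

test_that("simulator waves survive an EDF round trip within one step", {
  rec <- stream_to_recording(generate_stream(
    sim_scenario(duration_s = 20, seed = 9, events = FALSE)))
  waves <- names(rec$tracks)[vapply(rec$tracks, function(t)
    t$kind == "wave", logical(1))]
  rec <- drop_tracks(rec, setdiff(names(rec$tracks), waves))
  path <- withr::local_tempfile(fileext = ".edf")
  info <- export_edf(rec, path)
  back <- read_edf(path)
  for (i in seq_along(waves)) {
    key <- waves[i]
    tr <- rec$tracks[[key]]
    orig <- to_physical(tr$blocks[[1]]$counts, tr)
    bk <- back$tracks[[info$labels[key]]]
    got <- to_physical(bk$blocks[[1]]$counts[seq_along(orig)], bk)
    expect_lt(max(abs(got - orig)), tr$gain * 1.01, label = key)
  }
})
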