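test_that("write/read round trip reproduces the recording field by field", {
  rec <- small_recording()
  path <- withr::local_tempfile(fileext = ".vital")
  write_vital(rec, path)
  back <- read_vital(path)
  expect_recording_equal(rec, back)
  expect_false(attr(back, "truncated"))
})

test_that("an empty recording yields a valid header-only file", {
  rec <- vital_recording(metadata = c(format_version = "1"))
  path <- withr::local_tempfile(fileext = ".vital")
  write_vital(rec, path)
  back <- read_vital(path)
  expect_length(back$tracks, 0L)
  expect_equal(back$metadata, rec$metadata)
})

test_that("decompress-parse-reserialize is byte-stable", {
  rec <- small_recording()
  p1 <- withr::local_tempfile(fileext = ".vital")
  p2 <- withr::local_tempfile(fileext = ".vital")
  write_vital(rec, p1)
  write_vital(read_vital(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a file truncated mid-packet recovers all packets before the cut", {
  rec <- small_recording()
  path <- withr::local_tempfile(fileext = ".vital")
  info <- write_vital(rec, path, compress = FALSE)
  total_packets <- sum(info$n_packets)
  # chop 3 bytes off the final packet
  sz <- file.size(path)
  trunc_path <- withr::local_tempfile(fileext = ".vital")
  writeBin(readBin(path, "raw", sz - 3), trunc_path)
  expect_warning(back <- read_vital(trunc_path, compressed = FALSE),
                 "truncated")
  expect_true(attr(back, "truncated"))
  expect_equal(sum(attr(back, "n_packets")), total_packets - 1L)
  # track directory is still fully intact
  expect_setequal(names(back$tracks), names(rec$tracks))

  # truncated gzip stream: same recovery path
  gz <- withr::local_tempfile(fileext = ".vital")
  write_vital(rec, gz)
  gz_trunc <- withr::local_tempfile(fileext = ".vital")
  writeBin(readBin(gz, "raw", ceiling(file.size(gz) * 0.7)), gz_trunc)
  expect_warning(back2 <- read_vital(gz_trunc), "truncated")
  expect_true(attr(back2, "truncated"))
  expect_lt(sum(attr(back2, "n_packets")), total_packets)
})

test_that("bad magic and unknown kind codes raise format errors", {
  path <- withr::local_tempfile()
  writeBin(charToRaw("NOPEnope"), path)
  expect_error(read_vital(path), "bad magic")

  # craft a header whose single track carries kind code 9:
  # magic(4) version(1) rec_start(8) n_meta(2)=0 n_tracks(2)=1 id(2)
  # device "D" (2+1) name "N" (2+1) -> kind is the 26th byte
  rec <- vital_recording(list(make_numeric(device = "D", name = "N",
                                           times = T0, values = 1)),
                         rec_start = T0)
  p <- withr::local_tempfile()
  write_vital(rec, p, compress = FALSE)
  bytes <- readBin(p, "raw", file.size(p))
  expect_equal(as.integer(bytes[26L]), 2L)   # numeric kind code
  bytes[26L] <- as.raw(9L)
  writeBin(bytes, p)
  expect_error(read_vital(p, compressed = FALSE), "unknown track kind code 9")
})

test_that("scan_tracks matches full-read metadata without decoding payloads", {
  rec <- stream_to_recording(generate_stream(sim_scenario(duration_s = 30, seed = 7)))
  path <- withr::local_tempfile(fileext = ".vital")
  info <- write_vital(rec, path)
  dir <- scan_tracks(path)
  full <- read_vital(path)
  expect_equal(nrow(dir), length(full$tracks))
  expect_equal(attr(dir, "payload_bytes_decoded"), 0)
  expect_equal(attr(dir, "rec_start"), full$rec_start)
  expect_equal(attr(dir, "metadata"), full$metadata)
  for (i in seq_len(nrow(dir))) {
    tr <- full$tracks[[dir$key[i]]]
    expect_equal(dir$kind[i], tr$kind)
    expect_equal(dir$unit[i], tr$unit)
    expect_equal(dir$gain[i], tr$gain)
    expect_equal(dir$offset[i], tr$offset)
    if (tr$kind == "wave") expect_equal(dir$srate[i], tr$srate)
  }
  # packet counts agree with the writer's log
  expect_equal(dir$n_packets[match(names(info$n_packets), dir$key)],
               unname(info$n_packets))

  # degenerate file: events only
  ev <- vital_recording(list(event_track("EVENT", "EVENT",
                                         data.frame(time = T0, text = "x"))),
                        rec_start = T0)
  p2 <- withr::local_tempfile(fileext = ".vital")
  write_vital(ev, p2)
  d2 <- scan_tracks(p2)
  expect_equal(table(d2$kind)[["event"]], 1L)
  expect_false(any(d2$kind %in% c("wave", "numeric")))
})

test_that("compression never increases size on simulator output", {
  rec <- stream_to_recording(generate_stream(sim_scenario(duration_s = 60, seed = 3)))
  pc <- withr::local_tempfile(fileext = ".vital")
  pu <- withr::local_tempfile(fileext = ".raw")
  write_vital(rec, pc, compress = TRUE)
  write_vital(rec, pu, compress = FALSE)
  expect_lt(file.size(pc), file.size(pu))
})

test_that("selective reads skip unwanted payloads via length prefixes", {
  rec <- small_recording()
  path <- withr::local_tempfile(fileext = ".vital")
  write_vital(rec, path)
  sel <- read_vital(path, tracks = "Solar8000/HR")
  expect_equal(attr(sel, "wave_payload_bytes_decoded"), 0)
  expect_gt(attr(sel, "payload_bytes_decoded"), 0)
  expect_equal(sel$tracks[["Solar8000/HR"]]$samples$value,
               rec$tracks[["Solar8000/HR"]]$samples$value,
               tolerance = 1e-6)
  # undecoded tracks are present but empty
  expect_length(sel$tracks[["TramRac4A/ECG_II"]]$blocks, 0L)
})

test_that("round trips hold over randomised recordings", {
  for (seed in 1:8) {
    rec <- random_recording(seed)
    path <- withr::local_tempfile(fileext = ".vital")
    write_vital(rec, path)
    expect_recording_equal(rec, read_vital(path))
  }
})
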