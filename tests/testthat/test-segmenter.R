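test_that("a case starts when the 6th HR and SpO2 messages land inside one minute", {
  seg <- new_segmenter()
  started <- NULL
  for (t in seq(0, 20, by = 2)) {
    evs <- c(feed(seg, T0 + t, "Solar8000/HR", 70),
             feed(seg, T0 + t, "Solar8000/SPO2", 98))
    for (ev in evs) if (ev$type == "case-started") started <- ev$boundary$case_start
    if (!is.null(started)) break
  }
  expect_equal(started, T0 + 10)   # 6th message of each signal, strict "more than 5"
})

test_that("one signal alone never starts a case", {
  seg <- new_segmenter()
  evs <- list()
  for (t in seq(0, 600, by = 2))
    evs <- c(evs, feed(seg, T0 + t, "Solar8000/HR", 70))
  expect_length(evs, 0L)
})

test_that("closure fires the timeout after the later of the two last signals", {
  seg <- new_segmenter()
  for (t in seq(0, 1000, by = 2)) {
    feed(seg, T0 + t, "Solar8000/HR", 70)
    if (t <= 1000) feed(seg, T0 + t, "Solar8000/SPO2", 98)
  }
  feed(seg, T0 + 1005, "Solar8000/SPO2", 98)   # last SpO2 at 1005, last HR at 1000
  evs <- advance(seg, T0 + 4000)
  closed <- Filter(function(e) e$type == "case-closed", evs)
  expect_length(closed, 1L)
  expect_equal(closed[[1]]$boundary$case_end, T0 + 1605)
  expect_equal(closed[[1]]$boundary$end_reason, "timeout")
})

test_that("exactly 5 messages per minute never trigger; 6 always do", {
  # 5/min: one message every 12 s
  s5 <- segment_stream(hr_spo2_stream(seq(0, 1800, by = 12)))
  expect_length(s5$boundaries, 0L)
  # 6/min: every 10 s
  s6 <- segment_stream(hr_spo2_stream(seq(0, 1800, by = 10)))
  expect_length(s6$boundaries, 1L)
  expect_equal(s6$boundaries[[1]]$case_start, T0 + 50)
})

test_that("silence of 599 s keeps the case open; 600 s closes it", {
  mk <- function() {
    seg <- new_segmenter()
    for (t in seq(0, 100, by = 2)) {
      feed(seg, T0 + t, "Solar8000/HR", 70)
      feed(seg, T0 + t, "Solar8000/SPO2", 98)
    }
    seg
  }
  seg <- mk()
  expect_length(advance(seg, T0 + 100 + 599), 0L)
  seg2 <- mk()
  evs <- advance(seg2, T0 + 100 + 600)
  expect_equal(evs[[1]]$type, "case-closed")
  expect_equal(evs[[1]]$boundary$case_end, T0 + 700)
})

test_that("two activity bouts separated by 20 min give two cases", {
  st <- hr_spo2_stream(c(seq(0, 300, by = 2), seq(1500, 1800, by = 2)))
  s <- segment_stream(st)
  expect_length(s$boundaries, 2L)
  expect_equal(s$boundaries[[1]]$end_reason, "timeout")
  expect_equal(s$boundaries[[1]]$case_end, T0 + 300 + 600)
  expect_equal(s$boundaries[[2]]$case_start, T0 + 1510)
})

test_that("an empty stream yields no cases", {
  s <- segment_stream(data.frame(time = numeric(), key = character()))
  expect_length(s$boundaries, 0L)
})

test_that("split_by_date closes at local midnight and reopens immediately", {
  mid <- as.numeric(as.POSIXct("2016-06-16 00:00:00", tz = "UTC"))
  st <- hr_spo2_stream(seq(0, 7200, by = 2), t0 = mid - 3600)  # 23:00-01:00
  s <- segment_stream(st, segmenter_config(split_by_date = TRUE))
  expect_length(s$boundaries, 2L)
  expect_equal(s$boundaries[[1]]$case_end, mid)
  expect_equal(s$boundaries[[1]]$end_reason, "date-split")
  expect_equal(s$boundaries[[2]]$case_start, mid)
  # fragments rejoin: both cases cover the full message set
  expect_equal(sort(unique(s$assignment)), c(1L, 2L))
})

test_that("case starts match a brute-force window-counting oracle on random streams", {
  set.seed(11)
  for (i in 1:12) {
    times <- sort(sample(seq(0, 400, by = 1), sample(8:60, 1)))
    st <- hr_spo2_stream(times)
    s <- segment_stream(st)
    want <- oracle_case_start(st)
    got <- if (length(s$boundaries)) s$boundaries[[1]]$case_start else NA_real_
    expect_equal(got, want, info = paste("stream", i))
  }
})

test_that("segmentation is deterministic and respects case membership", {
  st <- hr_spo2_stream(c(seq(0, 200, by = 2), seq(1200, 1300, by = 2)))
  s1 <- segment_stream(st, segmenter_config(delete_between_cases = TRUE))
  s2 <- segment_stream(st, segmenter_config(delete_between_cases = TRUE))
  expect_identical(s1$boundaries, s2$boundaries)
  expect_identical(s1$assignment, s2$assignment)
  # deletion only ever hits messages outside every case interval
  for (k in seq_along(s1$boundaries)) {
    b <- s1$boundaries[[k]]
    inside <- st$time >= b$case_start & st$time <= b$case_end
    expect_true(all(!is.na(s1$assignment[inside])))
  }
})

test_that("time regressions are rejected", {
  seg <- new_segmenter()
  feed(seg, T0 + 10, "Solar8000/HR", 70)
  expect_error(feed(seg, T0 + 5, "Solar8000/HR", 70), "time-ordered")
  expect_error(advance(seg, T0), "backwards")
  expect_error(segmenter_config(start_count_threshold = 0), "positive")
})
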