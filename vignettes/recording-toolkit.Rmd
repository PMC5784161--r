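---
title: "Recording, segmenting and exporting multi-device vital-signs streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recording, segmenting and exporting multi-device vital-signs streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalrec)
```

## The problem

Intraoperative research needs vital-signs data at far higher resolution than
an anaesthesia information management system records: full-rate waveforms
(500 Hz ECG, 128 Hz EEG, 62.5 Hz capnography) together with the one- to
seven-second numeric parameters of every device at the bedside, all on a
single time axis. `vitalrec` is a desk-scale toolkit for that kind of data:
a lossless block-compressed container, an automatic case segmenter, editing
and export utilities, a filter plugin system, and — because this package is
developed and tested without operating-room hardware — a seeded simulator of
the device message streams themselves.

## Data model

A *recording* is one case file: a set of *tracks* keyed by `device/name`,
plus a record start time and free-form metadata (deliberately without site
identifiers). Tracks come in three kinds:

* **wave** — raw ADC counts in fixed-rate *blocks*. Counts are stored exactly
  as the digitiser produced them; the linear conversion
  `physical = gain * count + offset` is stored separately on the track, so no
  precision is ever lost to floating-point storage. A new block starts
  whenever the spacing between consecutive samples exceeds 1.5x the nominal
  interval: this tolerates transmission jitter while isolating genuine
  acquisition gaps (electrocautery interference is the classic cause).
* **numeric** — timestamped floats (heart rate, pressures, gas fractions, ...).
* **event** — timestamped annotation text.

The default digitiser model is a 10-bit converter spanning ±5 V with
count 0 at −5 V and count 1023 at +5 V, endpoints inclusive; the endpoint
convention is this package's own choice.

## Container format

`write_vital()` serialises the recording as a little-endian packet stream —
a self-describing header (track directory with units, conversion factors and
rates) followed by length-prefixed packets, one per wave block and one batch
per numeric/event track — and wraps the whole stream in a single gzip
member. Design choices that matter:

* **Timestamps** are milliseconds since `rec_start`, stored as 4-byte
  integers. Every catalog acquisition interval (down to 2 ms at 500 Hz) is
  exact on this grid, and offsets remain exact for recordings up to ~24 days,
  far beyond any case. Wave blocks store only their start time; sample times
  are implied by the rate.
* **Counts** are 16-bit signed integers (ample for 10-bit front-ends and
  typical monitor digitisers); numeric values are 32-bit floats, which covers
  the 3–4 significant digits devices actually emit.
* The **header is decodable without touching any payload**, and payloads can
  be skipped through their length prefixes. `scan_tracks()` exploits this to
  list a file without decoding a single sample byte, and `read_vital()` can
  selectively decode only queried tracks (the decoded-byte counters are
  exposed as attributes, and tests assert that numeric-only queries decode
  zero wave bytes).
* The writer is **canonical** (tracks sorted by key, deterministic packet
  order), so decompress → parse → re-serialise is byte-stable.
* A **truncated file** — a recording cut off by power loss, say — is read
  back up to the last complete packet, with a warning and a `truncated`
  attribute rather than a hard failure.
* The stream is one gzip member without internal sync points; partial
  recovery relies on tolerant decompression of the prefix, which the
  truncation tests exercise for both compressed and uncompressed streams.

One hour of the default simulated device mix (see below) serialises to
~28 MB of packets and compresses to ~4 MB on disk.

## Automatic case segmentation

The segmenter is an event-driven state machine fed timestamped messages. A
case **starts** at the first message at which *both* the heart-rate and the
oxygen-saturation signal have arrived **more than** `start_count_threshold`
(default 5) times within the trailing `start_window_s` (default 60 s) — i.e.
the 6th message of the later signal triggers, and each signal is counted
separately. The counting is evaluated at message arrivals; there is no
polling clock. A case **closes** once `stop_timeout_s` (default 600 s)
elapses after the later of the two signals' last message; the recorded case
end is `last_signal + timeout`, not the time the silence was noticed.

Two interpretation questions were left open by the rule's plain statement
and resolved as follows. First, whether "more than five times" counts the
two signals jointly or separately: this package counts each signal
separately and requires both to exceed the threshold, the stricter and
physiologically safer reading (a monitor standby emitting only HR must not
start a case). Second, what "separating cases by date" means: both readings
are implemented — with `split_by_date` a case crossing local midnight closes
at 00:00:00 and a new case opens immediately (fragments rejoin losslessly
with `merge_recordings()`), and the offline recording loop
(`record_session()`) additionally files case containers into date-named
folders.

Messages buffered in the start window *before* the trigger belong to the
case — they are valid patient data, and discarding them would lose the first
minute of monitoring. `delete_between_cases` discards only messages outside
every case interval. A dropped transport connection needs no special
handling: it simply pauses messages, and closure falls out of the timeout
rule.

## The simulator

`sim_scenario()` / `generate_stream()` emulate the device park without
hardware. The default roster is the standard simultaneous-recording mix:
seven 500 Hz waves (three ECG leads, plethysmogram, two arterial pressures,
central venous pressure), two 128 Hz EEG channels, and 90 numeric tracks
(patient monitor 24 @ 2 s, anaesthesia machine 40 @ 7 s, EEG monitor 8 @ 1 s,
cardiac-output monitor 6 @ 2 s, and two infusion pumps 6 each @ 1 s). The
90-track composition is declared in `device_catalog()`; generic `VENT_AUX*`
trends pad the anaesthesia machine to its catalog parameter count. The
62.5 Hz capnogram is in the catalog and used by the rate-fidelity tests, but
is not part of the default roster.

Waveforms are template pulse trains: sums of Gaussians per beat (ECG), a
skewed systolic pulse with a dicrotic bump (plethysmogram and arterial
pressure), a-c-v waves (CVP), an expiratory plateau (capnogram), and
AR(2)-filtered noise resonant near 10 Hz for the EEG. The stochastic element
is *beat-level*: seeded jitter of the RR interval (3% SD), per-beat
amplitude (3%), respiratory modulation and slow baseline drift — not
per-sample white noise on the periodic waves. That models what monitors
actually stream (filtered waveforms with beat-to-beat variability riding on
a quantised template) and is what makes the data compress like real
recordings. Numeric tracks are slow seeded sinusoidal drifts around a
resting baseline with small measurement noise, rounded to the one decimal a
device emits; pump volumes ramp. Waves are chunked into 1 s messages to
mimic streaming acquisition; a gap schedule removes messages per device,
emulating electrocautery dropouts, and the stream is byte-identical for a
fixed scenario.

What the simulator does **not** model: arrhythmias, artefact morphology
(probe dislodgement, flushes, cuff leaning), drug-driven haemodynamic
trends, or electrophysiological realism. Passing tests therefore demonstrate
the *mechanics* — rates, gaps, compression behaviour, segmentation — on
physiologically plausible signals, not clinical fidelity.

```{r sim-example}
sc <- sim_scenario(duration_s = 60, seed = 1)
rec <- simulate_recording(sc)
track_stats(rec$tracks[["TramRac4A/ECG_II"]])[c("n", "rate")]
```

## Editing, export, de-identification

`merge_recordings()` unifies fragments of one case: same-key tracks are
combined time-sorted, contiguous wave blocks re-joined under the same 1.5x
gap rule, and exact-timestamp duplicates resolved in favour of the earlier
fragment (fragments are chronological; the first write is the original
capture). `trim_recording()` keeps `[t0, t1)`, cutting wave blocks at the
nearest inside sample, and `split_recording()` is its partition inverse —
`merge(split(R, t))` reproduces `R` for any split point, which the property
tests check at random `t`.

Delimited export covers numeric tracks only (a 500 Hz wave in a CSV row per
sample would be absurd; waves go to EDF). The output grid runs from
`rec_start` at `interval_s` steps, and cells follow the missing-value
policy: `blank`, or `carry-forward` limited by `max_staleness_s` — a cell is
never filled from a sample older than the staleness bound. Import
auto-detects ISO-8601 versus relative-seconds time columns and reports
skipped cells.

EDF export picks the smallest data-record duration in {1, 2, 4, 8, 16} s
that makes samples-per-record integral for every exported rate (62.5 Hz →
2 s, 125 samples; 500 Hz + 128 Hz → 1 s). Physical min/max derive from each
track's gain/offset at its digital range, so counts pass through unchanged.
Gaps are filled with the track's physical *minimum* — never a mid-range
value, so a gap can't masquerade as signal — and logged to a sidecar TSV.
Patient fields default to `"X"`. Note that plain EDF carries a two-digit
year, so de-identified files anchored in 2100 display year "00".

`deidentify()` rebases every timestamp onto the fixed anchor
2100-01-01T00:00:00 UTC (the anchor's timezone is this package's choice, and
is recorded in the metadata convention). Times are rebased through their
offset from `rec_start`, so relative times are preserved exactly at the
container's millisecond precision. Metadata other than the device roster and
format version is blanked; event *text* is left untouched — if free text may
contain names, screen it separately. That residual risk is documented rather
than silently "solved".

## Filters

Filters are registered callables mapping input tracks to one new output
track; `apply_filter()` never mutates existing tracks and refuses an output
key that already exists. The built-in artifact filters are a rolling median
and rolling mean over a *centered time window* (default 60 s — the classic
one-minute median for monitor numerics sampled every few seconds). The
window shrinks at the series edges, so the output is defined at every input
timestamp without padding bias; an even count takes the mean of the two
middle values. The Surgical Pleth Index slot is deliberately a stub: its
formula is published elsewhere and is not reimplemented here, but the
plugin mechanism (`register_filter()`, `load_filter_dir()`) lets a user
supply it.

## Numerical choices and degenerate inputs

* Boundary comparisons on the time axis use small tolerances, and rolling
  windows rebase times to the series start first — absolute epoch seconds
  (~1.5e9) leave only ~0.25 µs of double precision, so naive epsilons
  misbehave at epoch magnitude.
* Empty tracks, empty recordings, empty streams, and trims that remove
  everything are all legal and covered by tests; a header-only container
  round-trips.
* Merge ties are broken deterministically (earlier input wins); the stream
  generator orders simultaneous messages by device then parameter, so
  segmentation and serialisation are reproducible bit-for-bit.
* Numeric values survive the container as 32-bit floats; tests compare them
  at that precision, and counts/times/metadata exactly.

## Problem sizes used in the test suite

The compression check writes the full one-hour default mix (about 13.5
million wave samples plus 162 000 numeric samples) for three seeds; the
remaining tests run on 20–600 s scenarios and randomised miniature
recordings, which exercise every code path in seconds. These sizes are the
package's own test design: the one-hour fixture is the condition under which
the hourly-size figure is stated, and nothing smaller would test it.

## Known limitations

* The container dialect is this package's own: compatible in spirit with
  block-compressed `.vital`-style files, not byte-compatible with any other
  program's layout.
* Plain EDF only — no EDF+ annotations; event tracks do not export to EDF.
* The segmenter recognises HR/SpO2 by parameter name (configurable), not by
  semantic device introspection.
* De-identification clears metadata and shifts times; it does not scrub
  event text.
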