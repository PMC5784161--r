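# vitalrec

High-resolution, time-synchronised vital-signs data — full-rate waveforms
alongside every slow numeric parameter of every device at the bedside — is
what intraoperative research needs and what routine clinical record systems
do not keep. `vitalrec` is an R toolkit for working with exactly that kind
of data at desk scale:

* a **lossless block-compressed container** for multi-rate physiological
  tracks: waveforms as raw ADC counts in gap-delimited blocks (physical
  value = `gain * count + offset`, with the conversion factors stored
  separately), numeric samples, and event annotations, all on one time axis,
  gzip-framed with a header that is readable without decoding a single
  sample;
* an **automatic case segmenter**: a new case starts when the heart-rate and
  oxygen-saturation signals each arrive more than five times within one
  minute, and closes 10 minutes after both signals disappear, with
  delete-between-cases and split-by-date options;
* **editing** (merge fragmented case files, trim, drop tracks),
  **export/import** (CSV/TSV with grid resampling and blank/carry-forward
  missing-value policies; plain EDF for waveforms), and batch **file
  utilities** including timestamp-shifting de-identification to the fixed
  anchor 2100-01-01;
* a **filter plugin system** with rolling-median/mean artifact filters over
  centered time windows;
* a seeded **device-stream simulator** (ECG, plethysmogram, arterial and
  venous pressures, capnogram, EEG, and 90 numeric tracks at their catalog
  intervals, with electrocautery-style gap injection) standing in for RS-232
  hardware — the test bed for everything above.

It is aimed at researchers who handle multi-device anaesthesia recordings
and at anyone who needs a transparent, scriptable reference implementation
of this recording workflow.

## Worked example

Simulate a 10-minute case, segment it, store it, filter it:

```r
library(vitalrec)

sc     <- sim_scenario(duration_s = 600, seed = 7)   # default device mix
stream <- generate_stream(sc)
nrow(stream)
#> [1] 29803

seg <- segment_stream(stream)
seg$boundaries[[1]]$case_start - sc$rec_start
#> [1] 10        # the 6th HR and SpO2 messages (2 s apart) land at t = 10 s

rec <- stream_to_recording(stream)
write_vital(rec, "case.vital")   # 100 tracks -> ~696 KB on disk

track_stats(rec$tracks[["TramRac4A/ECG_II"]])[c("n", "rate")]
#> $n
#> [1] 300000    # 600 s at 500 Hz
#> $rate
#> [1] 500

# one-minute rolling median, the standard artifact filter for monitor numerics
hr <- rec$tracks[["Solar8000/HR"]]$samples
filtered <- rolling_median(hr, window_s = 60)

# de-identify: rec_start moves to 2100-01-01, every interval preserved
deid <- deidentify(rec)
as.POSIXct(deid$rec_start, origin = "1970-01-01", tz = "UTC")
#> [1] "2100-01-01 UTC"

# list a file without decoding any sample payload
head(scan_tracks("case.vital")[, c("key", "kind", "unit", "srate")], 3)
#>             key    kind unit srate
#> 1 BISVista/ASYM numeric    %    NA
#> 2   BISVista/BC numeric /min    NA
#> 3  BISVista/BIS numeric         NA
```

The numbers mean: a 10-minute case with seven 500 Hz waves, two 128 Hz EEG
channels and 90 numeric tracks is ~30 000 messages and well under a
megabyte once compressed; the segmenter fires on the strict
more-than-five-per-minute rule; and header-only scans make batch work over
many files cheap.

A command-line twin of the utilities ships in `inst/cli/vitalrec`
(subcommands `sim`, `record`, `list`, `trks`, `recs`, `deid`, `merge`,
`trim`, `export-csv`, `export-edf`, `import-csv`, `filter`).

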