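# Catalog of emulated anaesthesia devices: parameter rosters, data kinds and
# acquisition intervals. Numeric intervals follow the supported-device
# catalog (patient monitor every 2 s, anaesthesia machine every 7 s, EEG
# monitor and infusion pumps every 1 s, cardiac-output monitor every 2 s);
# waveform rates are 500 Hz for the monitor's analog module, 62.5 Hz for the
# capnogram and 128 Hz per EEG channel.

# Physical display ranges per waveform kind; counts map linearly onto them.
WAVE_PHYS <- list(
  ecg   = list(unit = "mV",   lo = -5,   hi = 5),
  pleth = list(unit = "%",    lo = 0,    hi = 100),
  abp   = list(unit = "mmHg", lo = -50,  hi = 300),
  cvp   = list(unit = "mmHg", lo = -10,  hi = 40),
  capno = list(unit = "mmHg", lo = 0,    hi = 80),
  eeg   = list(unit = "uV",   lo = -250, hi = 250)
)

#' Conversion factors for a simulated waveform kind
#'
#' Maps the digitiser count range onto the kind's physical display range
#' (count `digital_min` -> `lo`, count `digital_max` -> `hi`, endpoints
#' inclusive), yielding the gain/offset stored on the track.
#'
#' @param kind One of `"ecg"`, `"pleth"`, `"abp"`, `"cvp"`, `"capno"`, `"eeg"`.
#' @param adc An [adc_spec()]; default 10-bit.
#' @return List with `unit`, `lo`, `hi`, `gain`, `offset`.
#' @export
wave_conversion <- function(kind, adc = adc_spec()) {
  p <- WAVE_PHYS[[kind]]
  if (is.null(p)) stop("unknown waveform kind '", kind, "'")
  gain <- (p$hi - p$lo) / (adc$digital_max - adc$digital_min)
  list(unit = p$unit, lo = p$lo, hi = p$hi,
       gain = gain, offset = p$lo - gain * adc$digital_min)
}

roster_row <- function(device, param, kind, unit, srate = NA_real_,
                       interval_s = NA_real_, lo = NA_real_, hi = NA_real_,
                       base = NA_real_, wave_kind = NA_character_,
                       trend = "flat") {
  data.frame(device = device, param = param, kind = kind, unit = unit,
             srate = srate, interval_s = interval_s, lo = lo, hi = hi,
             base = base, wave_kind = wave_kind, trend = trend,
             stringsAsFactors = FALSE)
}

num_rows <- function(device, interval_s, tab) {
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    roster_row(device, tab$param[i], "numeric", tab$unit[i],
               interval_s = interval_s, lo = tab$lo[i], hi = tab$hi[i],
               base = tab$base[i], trend = tab$trend[i])))
}

ntab <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(param = r[[1]], unit = r[[2]], lo = as.numeric(r[[3]]),
               hi = as.numeric(r[[4]]), base = as.numeric(r[[5]]),
               trend = if (length(r) > 5) r[[6]] else "flat",
               stringsAsFactors = FALSE)))
  df
}

#' Emulated device catalog
#'
#' Full roster of the simulated device park: a patient monitor (24 numerics
#' every 2 s) with its analog waveform module (seven 500 Hz waves), an
#' anaesthesia machine (62.5 Hz capnogram + 40 numerics every 7 s), a
#' two-channel 128 Hz EEG/depth-of-anaesthesia monitor (+ 8 numerics every
#' 1 s), a cardiac-output monitor (6 numerics every 2 s) and two
#' target-controlled infusion pumps (6 numerics each, every 1 s) — 90 numeric
#' tracks in total. Generic `VENT_AUX*` parameters pad the anaesthesia
#' machine to its catalog parameter count.
#'
#' @return A `data.frame`, one row per track: `device`, `param`, `kind`,
#'   `unit`, `srate`/`interval_s`, plausible range `lo`/`hi`, `base`
#'   (resting value), `wave_kind`, `trend` (`"flat"` or `"ramp"`).
#' @export
device_catalog <- function() {
  waves <- rbind(
    roster_row("TramRac4A", "ECG_I",  "wave", "mV",   srate = 500, wave_kind = "ecg"),
    roster_row("TramRac4A", "ECG_II", "wave", "mV",   srate = 500, wave_kind = "ecg"),
    roster_row("TramRac4A", "ECG_V5", "wave", "mV",   srate = 500, wave_kind = "ecg"),
    roster_row("TramRac4A", "PLETH",  "wave", "%",    srate = 500, wave_kind = "pleth"),
    roster_row("TramRac4A", "ART",    "wave", "mmHg", srate = 500, wave_kind = "abp"),
    roster_row("TramRac4A", "FEM",    "wave", "mmHg", srate = 500, wave_kind = "abp"),
    roster_row("TramRac4A", "CVP",    "wave", "mmHg", srate = 500, wave_kind = "cvp"),
    roster_row("Primus",    "CO2",    "wave", "mmHg", srate = 62.5, wave_kind = "capno"),
    roster_row("BISVista",  "EEG1",   "wave", "uV",   srate = 128, wave_kind = "eeg"),
    roster_row("BISVista",  "EEG2",   "wave", "uV",   srate = 128, wave_kind = "eeg"))
  for (i in seq_len(nrow(waves))) {
    cv <- wave_conversion(waves$wave_kind[i])
    waves$lo[i] <- cv$lo; waves$hi[i] <- cv$hi
  }

  solar <- ntab(
    list("HR", "/min", 30, 150, 72), list("SPO2", "%", 85, 100, 98),
    list("PR", "/min", 30, 150, 72), list("SPO2_PI", "%", 0.2, 10, 2.5),
    list("ST_I", "mm", -2, 2, 0.1), list("ST_II", "mm", -2, 2, 0.1),
    list("ST_V5", "mm", -2, 2, -0.1), list("ST_V1", "mm", -2, 2, 0),
    list("PVC", "/min", 0, 20, 0), list("RR", "/min", 4, 35, 12),
    list("NIBP_SBP", "mmHg", 70, 200, 120), list("NIBP_DBP", "mmHg", 35, 110, 70),
    list("NIBP_MBP", "mmHg", 50, 140, 88), list("ART_SBP", "mmHg", 70, 200, 120),
    list("ART_DBP", "mmHg", 35, 110, 70), list("ART_MBP", "mmHg", 50, 140, 88),
    list("CVP", "mmHg", 0, 25, 8), list("PA_SBP", "mmHg", 15, 45, 25),
    list("PA_DBP", "mmHg", 4, 20, 10), list("PA_MBP", "mmHg", 9, 30, 16),
    list("ETCO2", "mmHg", 20, 50, 35), list("FICO2", "mmHg", 0, 6, 0.5),
    list("TEMP1", "degC", 33, 39, 36.3), list("TEMP2", "degC", 33, 39, 36.0))
  stopifnot(nrow(solar) == 24L)

  primus_named <- ntab(
    list("MAC", "", 0, 2.5, 0.9), list("FIO2", "%", 21, 100, 50),
    list("ETO2", "%", 15, 95, 44), list("FIN2O", "%", 0, 70, 0),
    list("ETN2O", "%", 0, 70, 0), list("FISEV", "%", 0, 8, 2.2),
    list("ETSEV", "%", 0, 8, 2.0), list("FIDES", "%", 0, 18, 0),
    list("ETDES", "%", 0, 18, 0), list("FIISO", "%", 0, 5, 0),
    list("ETISO", "%", 0, 5, 0), list("ETCO2", "mmHg", 20, 50, 35),
    list("FICO2", "mmHg", 0, 6, 0.4), list("RR_VENT", "/min", 4, 30, 12),
    list("TV_INSP", "mL", 200, 800, 460), list("TV_EXP", "mL", 200, 800, 450),
    list("MV", "L/min", 2, 12, 5.4), list("PIP", "cmH2O", 8, 40, 18),
    list("PPLAT", "cmH2O", 6, 35, 16), list("PMEAN", "cmH2O", 3, 20, 8),
    list("PEEP", "cmH2O", 0, 15, 5), list("COMPL", "mL/cmH2O", 15, 90, 45),
    list("RESIST", "cmH2O/L/s", 3, 25, 10), list("FLOW_O2", "L/min", 0, 10, 1),
    list("FLOW_AIR", "L/min", 0, 10, 1), list("FLOW_N2O", "L/min", 0, 10, 0),
    list("FGF", "L/min", 0, 15, 2))
  primus_aux <- ntab2_aux(40L - nrow(primus_named))

  bis <- ntab(
    list("BIS", "", 0, 100, 45), list("SEF95", "Hz", 5, 30, 14),
    list("SR", "%", 0, 100, 0), list("EMG", "dB", 20, 55, 30),
    list("SQI", "%", 0, 100, 95), list("TOTPOW", "dB", 30, 100, 60),
    list("BC", "/min", 0, 30, 0), list("ASYM", "%", 0, 100, 50))

  vigileo <- ntab(
    list("CO", "L/min", 2, 10, 5.0), list("CI", "L/min/m2", 1.5, 5, 2.8),
    list("SV", "mL", 40, 120, 75), list("SVI", "mL/m2", 25, 65, 42),
    list("SVV", "%", 2, 25, 10), list("SVR", "dyn.s/cm5", 600, 2000, 1100))

  pump <- ntab(
    list("RATE", "mL/h", 0, 120, 20), list("VOL", "mL", 0, 500, 30, "ramp"),
    list("PRESS", "mmHg", 0, 600, 180), list("CP", "ug/mL", 0, 8, 3.2),
    list("CE", "ug/mL", 0, 8, 3.0), list("RVOL", "mL", 0, 60, 48))

  numerics <- rbind(
    num_rows("Solar8000", 2, solar),
    num_rows("Primus", 7, rbind(primus_named, primus_aux)),
    num_rows("BISVista", 1, bis),
    num_rows("Vigileo", 2, vigileo),
    num_rows("OrchestraA", 1, pump),
    num_rows("OrchestraB", 1, pump))
  stopifnot(nrow(numerics) == 90L)
  rbind(waves, numerics)
}

# Generic slow ventilator auxiliary trends padding the anaesthesia-machine
# roster to its catalog parameter count.
ntab2_aux <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(param = sprintf("VENT_AUX%02d", i), unit = "",
               lo = 0, hi = 100, base = 10 + 2 * i, trend = "flat",
               stringsAsFactors = FALSE)))
}

#' Default simulator roster
#'
#' The standard simultaneous-recording condition: seven 500 Hz waveform
#' tracks and two 128 Hz EEG tracks plus the 90 numeric tracks of the device
#' park. The 62.5 Hz capnogram wave is excluded by default but available via
#' `include_capno_wave`.
#'
#' @param include_capno_wave Also include the anaesthesia machine's 62.5 Hz
#'   capnography wave.
#' @return Roster `data.frame` (subset of [device_catalog()]).
#' @export
default_roster <- function(include_capno_wave = FALSE) {
  cat_df <- device_catalog()
  if (!include_capno_wave)
    cat_df <- cat_df[!(cat_df$device == "Primus" & cat_df$kind == "wave"), ]
  cat_df
}
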