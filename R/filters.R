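# Plugin system for derived tracks. A filter is a registered callable taking
# the recording's input tracks and a parameter list, and returning the
# samples of one new output track. Built-ins cover the rolling-statistic
# artifact filters; user filters are discovered from a directory of R files,
# mirroring a "filters-user" folder.

.filter_registry <- new.env(parent = emptyenv())

#' Register a filter implementation
#'
#' @param name Filter name (registry key).
#' @param fn Function `(inputs, params)` where `inputs` is a named list of
#'   `vital_track` objects and `params` the spec's parameter map; must return
#'   a `data.frame` with columns `time` and `value` (the output samples).
#' @return Invisibly, the name.
#' @export
register_filter <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .filter_registry)
  invisible(name)
}

#' List registered filters
#' @return Character vector of filter names.
#' @export
list_filters <- function() sort(ls(.filter_registry))

#' Load user filters from a directory
#'
#' Sources every `.R` file in `dir`; the files call [register_filter()] to
#' add their filters, mirroring a user filter folder scanned at startup.
#'
#' @param dir Directory of filter scripts.
#' @return Invisibly, the filters registered after loading.
#' @export
load_filter_dir <- function(dir) {
  for (f in list.files(dir, pattern = "\\.[rR]$", full.names = TRUE))
    sys.source(f, envir = new.env(parent = asNamespace("vitalrec")))
  invisible(list_filters())
}

#' Define a filter application
#'
#' @param name Registered filter name.
#' @param inputs Character vector of input track keys (`device/name`).
#' @param output Output track key (must differ from every input key).
#' @param unit Output unit label.
#' @param params Named list of filter parameters.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(name, inputs, output, unit = "", params = list()) {
  if (output %in% inputs) stop("output key must differ from all input keys")
  structure(list(name = name, inputs = inputs, output = output, unit = unit,
                 params = params), class = "filter_spec")
}

#' Apply a filter, appending one derived track
#'
#' Input tracks are passed to the registered callable; its output samples
#' become a new numeric track. Existing tracks are never modified, and
#' re-application is refused while the output key exists.
#'
#' @param recording A `vital_recording`.
#' @param spec A [filter_spec()].
#' @return The recording with exactly one new track.
#' @export
apply_filter <- function(recording, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  missing_in <- setdiff(spec$inputs, names(recording$tracks))
  if (length(missing_in))
    stop("missing input track(s): ", paste(missing_in, collapse = ", "))
  if (spec$output %in% names(recording$tracks))
    stop("output track '", spec$output, "' already exists")
  if (!exists(spec$name, envir = .filter_registry))
    stop("no registered filter named '", spec$name, "'")
  fn <- get(spec$name, envir = .filter_registry)
  out <- fn(recording$tracks[spec$inputs], spec$params)
  if (!is.data.frame(out) || !all(c("time", "value") %in% names(out)))
    stop("filter '", spec$name, "' must return a data.frame(time, value)")
  parts <- strsplit(spec$output, "/", fixed = TRUE)[[1L]]
  device <- if (length(parts) >= 2L) parts[1L] else "FILTER"
  name <- if (length(parts) >= 2L) paste(parts[-1L], collapse = "/") else spec$output
  new_track <- numeric_track(device, name, spec$unit,
                             out[order(out$time), , drop = FALSE])
  vital_recording(c(recording$tracks, list(new_track)),
                  rec_start = min(recording$rec_start,
                                  track_first_time(new_track), na.rm = TRUE),
                  metadata = recording$metadata)
}

# Window bounds of the centered time window [t_i - w/2, t_i + w/2]
# (inclusive, shrinking at the series edges). Times are rebased to the first
# sample so the boundary tolerance is meaningful at epoch magnitudes.
window_bounds <- function(times, window_s) {
  tt <- times - times[1L]
  h <- window_s / 2 + 1e-6
  lo <- findInterval(tt - h, tt) + 1L
  hi <- findInterval(tt + h, tt)
  list(lo = lo, hi = hi)
}

#' Rolling median over a centered time window
#'
#' The artifact filter of choice for monitor numerics (e.g. a 1-minute median
#' on data acquired every 5 s): each output value is the median of all
#' samples within `window_s / 2` seconds of the sample's own timestamp. The
#' window shrinks at the series edges (no padding), so the output is defined
#' at every input timestamp; an even sample count takes the mean of the two
#' middle values. A constant series passes through unchanged.
#'
#' @param samples `data.frame` with time-sorted columns `time` and `value`.
#' @param window_s Window length in seconds (> 0).
#' @return A `data.frame(time, value)` aligned with the input timestamps.
#' @export
rolling_median <- function(samples, window_s) {
  if (window_s <= 0) stop("window_s must be > 0")
  n <- nrow(samples)
  if (n == 0L) return(data.frame(time = numeric(), value = numeric()))
  b <- window_bounds(samples$time, window_s)
  v <- samples$value
  out <- vapply(seq_len(n), function(i)
    stats::median(v[b$lo[i]:b$hi[i]]), numeric(1))
  data.frame(time = samples$time, value = out)
}

#' Rolling mean over a centered time window
#'
#' @inheritParams rolling_median
#' @return A `data.frame(time, value)`.
#' @export
rolling_mean <- function(samples, window_s) {
  if (window_s <= 0) stop("window_s must be > 0")
  n <- nrow(samples)
  if (n == 0L) return(data.frame(time = numeric(), value = numeric()))
  b <- window_bounds(samples$time, window_s)
  cs <- cumsum(samples$value)
  tot <- cs[b$hi] - c(0, cs)[b$lo]
  data.frame(time = samples$time, value = tot / (b$hi - b$lo + 1L))
}

register_builtin_filters <- function() {
  register_filter("identity", function(inputs, params) inputs[[1L]]$samples)
  register_filter("rolling_median", function(inputs, params) {
    w <- params$window_s %||% 60
    rolling_median(inputs[[1L]]$samples, w)
  })
  register_filter("rolling_mean", function(inputs, params) {
    w <- params$window_s %||% 60
    rolling_mean(inputs[[1L]]$samples, w)
  })
  # Surgical Pleth Index: the published nociception index derived from the
  # plethysmogram. Its formula is proprietary to an external publication and
  # deliberately not reimplemented here; the plugin slot exists so a user
  # filter can provide it.
  register_filter("spi", function(inputs, params)
    stop("'spi' is a plugin stub: the SPI formula is defined in an external ",
         "publication and is not implemented; register a user filter to ",
         "provide it"))
}
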