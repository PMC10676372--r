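# Filtering and epoching primitives. All band filters are 4th-order
# Butterworth responses applied forward-backward (zero phase) unless
# requested otherwise; bandpasses are realized as a highpass/lowpass cascade,
# which is numerically stabler than a single 8-pole transfer function at the
# very low normalized corners used for slow potentials.

# Filter a numeric vector. low_hz = 0 means lowpass only; high_hz = fs/2
# means highpass only. A highpass corner with fewer than ~3 cycles in the
# record degenerates numerically; it is then realized as a linear detrend,
# which is the limit behaviour for record-scale corners (e.g. the 0.001 Hz
# clinical corner on a 540 s fragment).
filter_vector <- function(x, fs, low_hz, high_hz, zero_phase = TRUE, order = 4) {
  assert_finite(x, "signal")
  nyq <- fs / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyq)
    stopf("invalid band [%g, %g] Hz for fs = %g Hz", low_hz, high_hz, fs)
  apply1 <- function(x, flt) {
    if (zero_phase) signal::filtfilt(flt, x) else signal::filter(flt, x)
  }
  y <- x
  if (low_hz > 0) {
    if (low_hz * length(x) / fs < 3) {
      tt <- seq_along(y)
      y <- stats::residuals(stats::lm.fit(cbind(1, tt), y))
    } else {
      y <- apply1(y, signal::butter(order, low_hz / nyq, type = "high"))
    }
  }
  if (high_hz < nyq) {
    y <- apply1(y, signal::butter(order, high_hz / nyq, type = "low"))
  }
  as.numeric(y)
}

#' Band-filter a recording
#'
#' Applies a Butterworth band filter channel-wise. With `zero_phase = TRUE`
#' (default) the filter runs forward-backward, preserving peak latencies,
#' as required by triggered averaging and phase analysis.
#'
#' @param rec a `laminar_recording` or `ecog_recording` (or numeric vector,
#'   in which case `fs` must be given).
#' @param low_hz lower band edge in Hz; 0 requests a pure lowpass.
#' @param high_hz upper band edge in Hz; `fs/2` requests a pure highpass.
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @param fs sampling rate, only used when `rec` is a bare numeric vector.
#' @param order filter order (per pass).
#' @return an object of the same class as `rec` with filtered data
#'   (AC-coupled if the band excludes DC).
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, zero_phase = TRUE, fs = NULL,
                            order = 4) {
  if (is.numeric(rec) && is.null(dim(rec))) {
    if (is.null(fs)) stopf("fs required when filtering a bare vector")
    return(filter_vector(rec, fs, low_hz, high_hz, zero_phase, order))
  }
  out <- rec
  out$data <- t(apply(rec$data, 1, filter_vector, fs = rec$fs, low_hz = low_hz,
                      high_hz = high_hz, zero_phase = zero_phase, order = order))
  if (n_channels(rec) == 1) out$data <- matrix(out$data, nrow = 1)
  if (low_hz > 0) out$coupling <- "AC"
  out$meta$filter_band_hz <- c(low_hz, high_hz)
  out
}

#' Extract an epoch around a reference time
#'
#' Cuts the segment `[ref + start, ref + end]` out of a recording. The window
#' must lie entirely inside the record; out-of-range requests raise an error
#' rather than silently truncating.
#'
#' @param rec a recording.
#' @param ref_time_s reference event time (absolute seconds).
#' @param spec an [epoch_spec()] (or length-2 numeric `c(start, end)`).
#' @return a recording segment; its metadata records the reference time and
#'   window used.
#' @export
epoch_extract <- function(rec, ref_time_s, spec) {
  if (is.numeric(spec) && length(spec) == 2) spec <- epoch_spec(spec[1], spec[2])
  i1 <- time_to_index(ref_time_s + spec$start_s, rec$t0, rec$fs)
  i2 <- time_to_index(ref_time_s + spec$end_s, rec$t0, rec$fs) - 1L
  if (i1 < 1L || i2 > n_samples(rec))
    stopf("epoch [%g, %g] s around t = %g s exceeds record bounds [%g, %g] s",
          spec$start_s, spec$end_s, ref_time_s, rec$t0, rec$t0 + rec_duration(rec))
  out <- rec
  out$data <- rec$data[, i1:i2, drop = FALSE]
  out$t0 <- rec$t0 + (i1 - 1L) / rec$fs
  out$meta$epoch <- list(ref_time_s = ref_time_s, start_s = spec$start_s,
                         end_s = spec$end_s)
  out
}

#' Event-triggered average
#'
#' Averages fixed windows around trigger times, channel-wise. Triggers whose
#' window does not fit inside the record are dropped and the number actually
#' used is reported.
#'
#' @param rec a recording.
#' @param trigger_times_s trigger times (absolute seconds).
#' @param window an [epoch_spec()] or `c(start, end)` offsets in seconds.
#' @return list with `average` (channels x window-samples matrix), `time_s`
#'   (window time axis relative to the trigger) and `n_used`.
#' @export
triggered_average <- function(rec, trigger_times_s, window) {
  if (is.numeric(window) && length(window) == 2) window <- epoch_spec(window[1], window[2])
  nw <- as.integer(round((window$end_s - window$start_s) * rec$fs))
  offs <- as.integer(round(window$start_s * rec$fs))
  starts <- time_to_index(trigger_times_s, rec$t0, rec$fs) + offs
  ok <- starts >= 1L & (starts + nw - 1L) <= n_samples(rec)
  if (!any(ok)) stopf("no trigger has a full [%g, %g] s window inside the record",
                      window$start_s, window$end_s)
  starts <- starts[ok]
  acc <- matrix(0, n_channels(rec), nw)
  for (s in starts) acc <- acc + rec$data[, s:(s + nw - 1L), drop = FALSE]
  list(average = acc / length(starts),
       time_s = window$start_s + (seq_len(nw) - 1L) / rec$fs,
       n_used = length(starts))
}

#' Sliding-window median filter
#'
#' Running median with a window given in seconds; realizes "lowpass < f Hz
#' median filter" prescriptions as a window of 1/f seconds. Robustly removes
#' action potentials from membrane-potential traces while following slow
#' depolarizations without lag (the centered median of a monotone ramp is the
#' ramp itself).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 5 s, i.e. < 0.2 Hz).
#' @return filtered vector, same length.
#' @export
sliding_median <- function(x, fs, window_s = 5) {
  k <- as.integer(round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}
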