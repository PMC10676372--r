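# Intracellular analysis: field-potential correction of the membrane
# potential, action-potential detection, depolarization / block metrics and
# UP-state amplitudes.

#' Correct the membrane potential for extracellular voltage shifts
#'
#' Subtracts the field potential of the probe channel nearest to the cell
#' from the recorded membrane potential; during an SD the extracellular DC
#' shift otherwise contaminates the apparent depolarization.
#'
#' @param trace an `intracellular_trace`.
#' @param rec the concurrent `laminar_recording`.
#' @param channel probe channel to subtract; default the channel nearest the
#'   cell depth (ties resolved to the shallower channel).
#' @return the trace with corrected `em`; the channel used is recorded in
#'   the metadata.
#' @export
correct_membrane_potential <- function(trace, rec, channel = NULL) {
  channel <- channel %||% nearest_channel(rec, trace$cell_depth_um)
  t_em <- trace$t0 + (seq_along(trace$em) - 1) / trace$fs
  t_fp <- rec_times(rec)
  if (t_em[1] < t_fp[1] - 1e-3 || t_em[length(t_em)] > t_fp[length(t_fp)] + 1e-3)
    stopf("membrane and field-potential time bases misaligned beyond 1 ms")
  fp <- if (abs(trace$fs - rec$fs) < 1e-9 && abs(trace$t0 - rec$t0) < 0.5 / rec$fs &&
            length(trace$em) == n_samples(rec)) {
    rec$data[channel, ]
  } else {
    stats::approx(t_fp, rec$data[channel, ], xout = t_em, rule = 2)$y
  }
  out <- trace
  out$em <- trace$em - fp
  out$meta$fp_channel <- channel
  out$meta$fp_corrected <- TRUE
  out
}

#' Detect action potentials
#'
#' Events exceeding 5 mV in the 50 Hz high-passed membrane potential; event
#' times are the peaks, with a 2 ms dead time.
#'
#' @param em membrane potential (mV) or an `intracellular_trace`.
#' @param fs sampling rate (Hz, >= 1 kHz); taken from the trace if given.
#' @param threshold_mv detection threshold.
#' @param dead_time_s minimum separation between APs.
#' @return AP peak times in seconds (relative to the trace start plus its
#'   `t0`).
#' @export
detect_action_potentials <- function(em, fs = NULL, threshold_mv = 5,
                                     dead_time_s = 0.002) {
  t0 <- 0
  if (inherits(em, "intracellular_trace")) {
    fs <- em$fs
    t0 <- em$t0
    em <- em$em
  }
  if (is.null(fs)) stopf("fs required")
  if (fs < 1000) stopf("AP detection needs fs >= 1 kHz")
  hp <- filter_vector(em, fs, 50, fs / 2)
  pk <- local_maxima(hp)
  pk <- pk[hp[pk] > threshold_mv]
  if (length(pk) > 1) {
    keep <- enforce_separation((pk - 1) / fs, hp[pk], dead_time_s)
    pk <- pk[keep]
  }
  t0 + (pk - 1) / fs
}

# Segment AP times into bursts: runs where the instantaneous rate (inverse
# inter-spike interval) stays at or above rate_hz.
ap_bursts <- function(ap_times, rate_hz = 5) {
  if (length(ap_times) < 2) return(list())
  isi <- diff(ap_times)
  joined <- isi <= 1 / rate_hz
  bursts <- list()
  start <- NULL
  for (i in seq_along(joined)) {
    if (joined[i] && is.null(start)) start <- i
    if ((!joined[i] || i == length(joined)) && !is.null(start)) {
      end <- if (joined[i]) i + 1L else i
      bursts[[length(bursts) + 1L]] <- ap_times[start:end]
      start <- NULL
    }
  }
  bursts
}

#' Depolarization and block metrics of a cell during an SD
#'
#' Works on the slow (< 0.2 Hz, 5 s sliding-median) component of the
#' corrected membrane potential. The depolarization-block threshold is the
#' slow potential at the last AP before a silence of at least 5 s that
#' begins while the potential is still rising; firing is "sustained" when
#' APs span at least 80 % of the SD window.
#'
#' @param em_corr corrected membrane potential (mV) or `intracellular_trace`.
#' @param fs sampling rate (taken from the trace if given).
#' @param ap_times AP times (s), e.g. from [detect_action_potentials()].
#' @param sd_window `c(start, end)` seconds of the SD at this depth.
#' @param cell_depth_um soma depth.
#' @param stop_depth_um SD stop depth (for the cell-to-stop distance).
#' @param rest_window baseline window for the resting potential; default the
#'   30 s preceding the SD window.
#' @param silence_s minimum AP silence qualifying as block.
#' @param t0 trace start time when `em_corr` is a bare vector.
#' @return a `cell_sd_metrics` list: `rest_mv`, `peak_em_mv`,
#'   `depol_from_rest_mv`, `block_threshold_mv` (NA if no block),
#'   `sustained_firing`, `ap_burst_durations_s`, `distance_to_stop_um`
#'   (cell depth minus stop depth), `n_aps_sd`.
#' @export
depolarization_metrics <- function(em_corr, fs = NULL, ap_times, sd_window,
                                   cell_depth_um = NA, stop_depth_um = NA,
                                   rest_window = NULL, silence_s = 5, t0 = 0) {
  if (inherits(em_corr, "intracellular_trace")) {
    fs <- em_corr$fs
    t0 <- em_corr$t0
    em_corr <- em_corr$em
  }
  if (is.null(fs)) stopf("fs required")
  slow <- sliding_median(em_corr, fs, 5)
  tt <- t0 + (seq_along(slow) - 1) / fs
  rest_window <- rest_window %||% c(max(tt[1], sd_window[1] - 35), sd_window[1] - 5)
  rest <- stats::median(slow[tt >= rest_window[1] & tt <= rest_window[2]])
  in_sd <- tt >= sd_window[1] & tt <= sd_window[2]
  if (!any(in_sd)) stopf("SD window outside the trace")
  peak <- max(slow[in_sd])
  aps_sd <- ap_times[ap_times >= sd_window[1] & ap_times <= sd_window[2]]
  block <- NA_real_
  if (length(ap_times) > 0) {
    gaps_after <- c(diff(ap_times), Inf)
    at_idx <- pmin(pmax(time_to_index(ap_times, t0, fs), 1L), length(slow))
    for (i in seq_along(ap_times)) {
      if (ap_times[i] < sd_window[1] || ap_times[i] > sd_window[2]) next
      if (gaps_after[i] < silence_s) next
      i1 <- at_idx[i]
      i2 <- min(length(slow), i1 + as.integer(fs))
      # qualify only when the slow potential is still rising and the cell is
      # already depolarized well above rest (a true block trajectory)
      rising <- slow[i2] > slow[i1] + 0.5 && slow[i1] > rest + 5
      if (rising) {
        block <- slow[i1]
        break
      }
    }
  }
  sustained <- length(aps_sd) >= 2 &&
    (max(aps_sd) - min(aps_sd)) >= 0.8 * diff(sd_window)
  bursts <- ap_bursts(ap_times)
  durs <- vapply(bursts, function(b) max(b) - min(b), numeric(1))
  structure(list(rest_mv = rest, peak_em_mv = peak,
                 depol_from_rest_mv = peak - rest, block_threshold_mv = block,
                 sustained_firing = sustained, ap_burst_durations_s = durs,
                 distance_to_stop_um = cell_depth_um - stop_depth_um,
                 n_aps_sd = length(aps_sd)),
            class = "cell_sd_metrics")
}

#' @export
print.cell_sd_metrics <- function(x, ...) {
  cat(sprintf(
    "<cell_sd_metrics> rest %.1f mV, peak %.1f mV (depol %.1f mV), block %s, %s firing\n",
    x$rest_mv, x$peak_em_mv, x$depol_from_rest_mv,
    if (is.na(x$block_threshold_mv)) "none" else sprintf("at %.1f mV", x$block_threshold_mv),
    if (isTRUE(x$sustained_firing)) "sustained" else "transient"))
  invisible(x)
}

#' UP-state amplitude of the membrane potential
#'
#' UP-state-triggered average of the membrane potential over [-0.5, 1] s
#' around each trigger; the amplitude is the peak depolarization after the
#' trigger minus the mean of the [-0.5, -0.2] s baseline. With fewer than 5
#' usable triggers only the per-event amplitudes are returned.
#'
#' @param em_corr corrected membrane potential (vector or trace).
#' @param fs sampling rate (from the trace if given).
#' @param up_times trigger times (s), e.g. from [detect_up_states()].
#' @param window window around the trigger (s).
#' @param baseline baseline interval within the window (s).
#' @param t0 trace start time for bare vectors.
#' @return list with `amplitudes_mv` (per usable trigger), `mean_amplitude_mv`
#'   (NA when < 5 triggers), `n_used`, `average` (triggered-average waveform),
#'   `time_s`.
#' @export
up_state_amplitude <- function(em_corr, fs = NULL, up_times, window = c(-0.5, 1),
                               baseline = c(-0.5, -0.2), t0 = 0) {
  if (inherits(em_corr, "intracellular_trace")) {
    fs <- em_corr$fs
    t0 <- em_corr$t0
    em_corr <- em_corr$em
  }
  if (is.null(fs)) stopf("fs required")
  nw <- as.integer(round(diff(window) * fs))
  offs <- as.integer(round(window[1] * fs))
  rel_t <- window[1] + (seq_len(nw) - 1) / fs
  base_i <- rel_t >= baseline[1] & rel_t <= baseline[2]
  post_i <- rel_t >= 0
  starts <- time_to_index(up_times, t0, fs) + offs
  ok <- starts >= 1L & starts + nw - 1L <= length(em_corr)
  starts <- starts[ok]
  if (length(starts) == 0) stopf("no usable UP-state trigger")
  amps <- numeric(length(starts))
  acc <- numeric(nw)
  for (k in seq_along(starts)) {
    seg <- em_corr[starts[k]:(starts[k] + nw - 1L)]
    acc <- acc + seg
    amps[k] <- max(seg[post_i]) - mean(seg[base_i])
  }
  avg <- acc / length(starts)
  list(amplitudes_mv = amps,
       mean_amplitude_mv = if (length(starts) >= 5)
         max(avg[post_i]) - mean(avg[base_i]) else NA_real_,
       n_used = length(starts), average = avg, time_s = rel_t)
}
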