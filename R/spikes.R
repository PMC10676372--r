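# Multi-unit spike detection with an SD-adaptive threshold, MUA change and
# burst metrics, three-zone laminar mapping.
#
# The spike band (250-4000 Hz) is isolated with a zero-phase multiresolution
# filter built on the Daubechies-4 scaling kernel (a-trous scheme, kernel
# applied forward-backward per level): detail levels whose dyadic bands
# intersect 250-4000 Hz are summed. The detection threshold is 4 STD of the
# quietest 100 s control fragment; during an SD it adapts with the
# high-frequency (> 4 kHz reference band) noise level so that the
# impedance-driven noise increase does not masquerade as spikes.

# db4 scaling filter, normalized to sum 1 (smoothing kernel).
.db4_h <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690) / sqrt(2)

# Zero-phase smoothing with the (level-j upsampled) db4 scaling kernel.
atrous_smooth <- function(x, j) {
  h <- .db4_h
  if (j > 1) {
    hu <- numeric((length(h) - 1) * 2^(j - 1) + 1)
    hu[seq(1, length(hu), by = 2^(j - 1))] <- h
    h <- hu
  }
  pad <- length(h)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(length(x) - pad + 1):length(x)]))
  y <- stats::filter(xp, h, sides = 2)
  y <- stats::filter(y, rev(h), sides = 2)
  as.numeric(y[(pad + 1):(pad + length(x))])
}

#' Spike-band filter (Daubechies multiresolution)
#'
#' Decomposes the trace into dyadic detail levels with the db4 scaling
#' kernel applied zero-phase (a-trous scheme) and reconstructs the sum of
#' the levels covering `band`. Level j spans fs/2^(j+1) to fs/2^j.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band target band (Hz), default 250-4000.
#' @return band-limited trace, same length.
#' @export
spike_band_filter <- function(x, fs, band = c(250, 4000)) {
  assert_finite(x, "wideband signal")
  a <- x
  out <- numeric(length(x))
  jmax <- max(1L, floor(log2(fs / max(band[1], 1))) - 1L)
  for (j in seq_len(jmax)) {
    a_next <- atrous_smooth(a, j)
    d <- a - a_next
    f_hi <- fs / 2^j
    f_lo <- fs / 2^(j + 1)
    if (f_lo < band[2] && f_hi > band[1]) out <- out + d
    a <- a_next
  }
  out
}

# Reference band above the spike band: > 4 kHz when the sampling rate
# supports it, otherwise the top octave below Nyquist (desk-scale fallback).
reference_band_trace <- function(x, fs) {
  if (fs > 8000 * 1.001) {
    hp <- min(4000, fs / 2 * 0.8)
    filter_vector(x, fs, hp, fs / 2)
  } else {
    filter_vector(x, fs, fs / 4, fs / 2)
  }
}

# Quietest control fragment: sliding window minimizing RMS.
quietest_fragment <- function(x, fs, len_s = 100, hop_s = 10) {
  nwin <- as.integer(len_s * fs)
  if (length(x) < nwin) stopf("control epoch shorter than %g s", len_s)
  hop <- as.integer(hop_s * fs)
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  cs <- cumsum(c(0, x^2))
  rms <- (cs[starts + nwin] - cs[starts]) / nwin
  s <- starts[which.min(rms)]
  s:(s + nwin - 1L)
}

#' Detect multi-unit spikes with an SD-adaptive threshold
#'
#' Spikes are negative local minima of the 250-4000 Hz trace below
#' -threshold with a 1 ms dead time. The base threshold is
#' `threshold_k` x STD of the quietest 100 s control fragment. Within SD
#' windows an SD-specific threshold is used instead:
#' `threshold_k x STD_ref(window) x (STD_band(control) / STD_ref(control))`,
#' so the noise increase during the SD raises the threshold proportionally
#' (one adaptive threshold per SD).
#'
#' @param rec_wide wideband `laminar_recording` (fs >= 8 kHz).
#' @param control_epoch `c(start, end)` absolute seconds before the first SD
#'   (>= 100 s).
#' @param sd_windows list of `c(start, end)` windows in which the adaptive
#'   threshold applies (e.g. around each SD), or NULL.
#' @param threshold_k threshold multiplier (STDs).
#' @param adaptive use the adaptive threshold inside `sd_windows`; when
#'   FALSE the base threshold is used throughout.
#' @param band spike band (Hz).
#' @return list of `spike_train` objects (one per channel): `channel`,
#'   `times_s`, `amplitudes_mv`, `threshold_mv` (per spike), `base_threshold_mv`.
#' @export
detect_spikes <- function(rec_wide, control_epoch, sd_windows = NULL,
                          threshold_k = 4, adaptive = TRUE, band = c(250, 4000)) {
  fs <- rec_wide$fs
  if (fs < 8000) stopf("wideband fs %g Hz too low: the reference band needs >= 8 kHz", fs)
  if (diff(control_epoch) < 100) stopf("control epoch must be >= 100 s")
  out <- vector("list", n_channels(rec_wide))
  for (m in seq_len(n_channels(rec_wide))) {
    x <- rec_wide$data[m, ]
    sb <- spike_band_filter(x, fs, band)
    c1 <- time_to_index(control_epoch[1], rec_wide$t0, fs)
    c2 <- min(length(sb), time_to_index(control_epoch[2], rec_wide$t0, fs))
    qi <- quietest_fragment(sb[c1:c2], fs) + c1 - 1L
    sigma0 <- stats::sd(sb[qi])
    base_thr <- threshold_k * sigma0
    thr <- rep(base_thr, length(sb))
    if (adaptive && length(sd_windows) > 0) {
      hf <- reference_band_trace(x, fs)
      sigma_hf0 <- stats::sd(hf[qi])
      ratio0 <- sigma0 / sigma_hf0
      # one threshold per SD: reference-band STD over that SD's window,
      # mapped back to the spike band with the control-period ratio
      for (w in sd_windows) {
        i1 <- max(1L, time_to_index(w[1], rec_wide$t0, fs))
        i2 <- min(length(sb), time_to_index(w[2], rec_wide$t0, fs))
        thr[i1:i2] <- threshold_k * stats::sd(hf[i1:i2]) * ratio0
      }
    }
    mins <- local_minima(sb)
    mins <- mins[sb[mins] < -thr[mins]]
    if (length(mins) > 1) {
      keep <- enforce_separation((mins - 1) / fs, -sb[mins], 0.001)
      mins <- mins[keep]
    }
    out[[m]] <- structure(list(channel = m,
                               times_s = rec_wide$t0 + (mins - 1) / fs,
                               amplitudes_mv = sb[mins],
                               threshold_mv = thr[mins],
                               base_threshold_mv = base_thr),
                          class = "spike_train")
  }
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> channel %d: %d spikes, base threshold %.4g mV\n",
              x$channel, length(x$times_s), x$base_threshold_mv))
  invisible(x)
}

#' Per-channel MUA change across an SD
#'
#' Ratio of mean multi-unit rates between `[-25,-10]` s before the earliest
#' SD onset and `[0,15]` s after the deepest onset, with a per-channel
#' paired signed-rank test on 1 s binned rates.
#'
#' @param spike_times list of spike-time vectors (s), one per channel, or a
#'   list of `spike_train`s.
#' @param sd_event an `sd_event` (uses `earliest_onset_s`/`deepest_onset_s`),
#'   or a list with those fields.
#' @param pre_window,sd_window offsets (s) relative to the earliest/deepest
#'   onsets respectively.
#' @return data frame: `channel`, `pre_rate_hz`, `sd_rate_hz`, `ratio`
#'   (NA and `undefined = TRUE` when the pre window has no spikes),
#'   `p_value`.
#' @export
mua_change <- function(spike_times, sd_event, pre_window = c(-25, -10),
                       sd_window = c(0, 15)) {
  times_of <- function(s) if (inherits(s, "spike_train")) s$times_s else s
  t_pre <- sd_event$earliest_onset_s + pre_window
  t_sd <- sd_event$deepest_onset_s + sd_window
  rows <- lapply(seq_along(spike_times), function(m) {
    st <- times_of(spike_times[[m]])
    n_pre <- sum(st >= t_pre[1] & st < t_pre[2])
    n_sd <- sum(st >= t_sd[1] & st < t_sd[2])
    pre_rate <- n_pre / diff(pre_window)
    sd_rate <- n_sd / diff(sd_window)
    bins_pre <- graphics::hist(st[st >= t_pre[1] & st < t_pre[2]],
                               breaks = seq(t_pre[1], t_pre[2], by = 1),
                               plot = FALSE)$counts
    bins_sd <- graphics::hist(st[st >= t_sd[1] & st < t_sd[2]],
                              breaks = seq(t_sd[1], t_sd[2], by = 1),
                              plot = FALSE)$counts
    nb <- min(length(bins_pre), length(bins_sd))
    p <- if (all(bins_pre[1:nb] == bins_sd[1:nb])) 1 else
      suppressWarnings(stats::wilcox.test(bins_sd[1:nb], bins_pre[1:nb],
                                          paired = TRUE, exact = FALSE))$p.value
    data.frame(channel = m, pre_rate_hz = pre_rate, sd_rate_hz = sd_rate,
               ratio = if (n_pre == 0) NA_real_ else sd_rate / pre_rate,
               undefined = n_pre == 0, p_value = p)
  })
  do.call(rbind, rows)
}

#' Duration of MUA excitation episodes
#'
#' Total time the smoothed firing rate (100 ms bins, 3-bin moving average)
#' spends above the control mean + 3 STD, within an SD window.
#'
#' @param spike_times spike times (s) or a `spike_train`.
#' @param control_epoch `c(start, end)` seconds (>= 60 s).
#' @param sd_window `c(start, end)` seconds to evaluate.
#' @param bin_s rate bin width.
#' @return excitation duration in seconds.
#' @export
burst_duration <- function(spike_times, control_epoch, sd_window, bin_s = 0.1) {
  if (inherits(spike_times, "spike_train")) spike_times <- spike_times$times_s
  if (diff(control_epoch) < 60) stopf("control epoch must be >= 60 s")
  if (length(spike_times) == 0) return(0)
  rate_in <- function(w) {
    br <- seq(w[1], w[2], by = bin_s)
    cnt <- graphics::hist(spike_times[spike_times >= w[1] & spike_times < w[2]],
                          breaks = br, plot = FALSE)$counts / bin_s
    moving_average(cnt, 3L)
  }
  ctl <- rate_in(control_epoch)
  thr <- mean(ctl) + 3 * stats::sd(ctl)
  sdr <- rate_in(sd_window)
  sum(sdr > thr) * bin_s
}

#' Three-zone laminar profile of SD-related activity change
#'
#' Pools per-channel delta-power, gamma-power and MUA SD/pre ratios across
#' SDs, aligned on relative depth (channel depth minus SD stop depth), and
#' tests each 100 um bin with a Wilcoxon signed-rank test of log-ratio
#' against 0. Bins are labelled `depressed` (significant MUA decrease),
#' `subsd_excited` (significant MUA and gamma increase with delta decrease)
#' or `unchanged`; the sub-SD excitation band borders are the contiguous
#' run of excited bins.
#'
#' @param per_channel data frame with columns `sd_id`, `depth_um`,
#'   `stop_depth_um`, `delta_ratio`, `gamma_ratio`, `mua_ratio` (one row per
#'   SD x channel).
#' @param bin_um relative-depth bin width (default the electrode spacing).
#' @param alpha significance level.
#' @param min_n minimum pooled SDs per bin; sparser bins are dropped
#'   (default 6, the smallest n whose signed-rank test can reach p <= 0.05).
#' @return a `zone_profile`: data frame (`rel_depth_um`, `n`, medians and p
#'   per measure, `zone`) with attributes `band_top_um`/`band_bottom_um`
#'   (sub-SD band borders, relative to the stop depth) and
#'   `peak_mua_increase`.
#' @export
zone_profile <- function(per_channel, bin_um = 100, alpha = 0.05, min_n = 6) {
  req <- c("sd_id", "depth_um", "stop_depth_um", "delta_ratio", "gamma_ratio",
           "mua_ratio")
  if (!all(req %in% names(per_channel))) stopf("missing columns: %s",
    paste(setdiff(req, names(per_channel)), collapse = ", "))
  if (length(unique(per_channel$sd_id)) < 2) stopf("need pooled SDs (>= 2)")
  rel <- round((per_channel$depth_um - per_channel$stop_depth_um) / bin_um) * bin_um
  test_med <- function(x) {
    x <- x[is.finite(x) & x > 0]
    if (length(x) < min_n) return(c(NA_real_, NA_real_))
    p <- if (stats::sd(log(x)) == 0 && all(log(x) == 0)) 1 else
      suppressWarnings(stats::wilcox.test(log(x), mu = 0, exact = FALSE))$p.value
    c(stats::median(x), p)
  }
  bins <- sort(unique(rel))
  bins <- bins[vapply(bins, function(b) sum(rel == b), integer(1)) >= min_n]
  rows <- lapply(bins, function(b) {
    idx <- which(rel == b)
    d <- test_med(per_channel$delta_ratio[idx])
    g <- test_med(per_channel$gamma_ratio[idx])
    mu <- test_med(pmax(per_channel$mua_ratio[idx], 1e-6))
    data.frame(rel_depth_um = b, n = length(idx),
               delta_median = d[1], delta_p = d[2],
               gamma_median = g[1], gamma_p = g[2],
               mua_median = mu[1], mua_p = mu[2])
  })
  df <- do.call(rbind, rows)
  zone <- rep("unchanged", nrow(df))
  sig <- function(p) !is.na(p) & p <= alpha
  dep <- sig(df$mua_p) & df$mua_median < 1
  exc <- sig(df$mua_p) & df$mua_median > 1 & sig(df$gamma_p) & df$gamma_median > 1 &
    sig(df$delta_p) & df$delta_median < 1
  zone[dep] <- "depressed"
  zone[exc] <- "subsd_excited"
  mixed <- sig(df$mua_p) & df$mua_median > 1 & !exc
  zone[mixed] <- "mixed"
  df$zone <- zone
  band_top <- band_bottom <- NA_real_
  if (any(exc)) {
    runs <- rle(df$zone == "subsd_excited")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    li <- which(runs$values)
    best <- li[which.max(runs$lengths[li])]
    band_top <- df$rel_depth_um[starts[best]]
    band_bottom <- df$rel_depth_um[ends[best]]
  }
  structure(df, class = c("zone_profile", "data.frame"),
            band_top_um = band_top, band_bottom_um = band_bottom,
            peak_mua_increase = if (any(exc)) max(df$mua_median[exc]) else NA_real_)
}
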