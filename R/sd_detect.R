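# SD onset detection from the derivative of the slow potential, and vertical
# stop-depth determination on laminar probes.
#
# An SD appears as a slow negative DC shift; its onset is localized at the
# peak of the (negative) first derivative of the low-passed slow potential
# (rat: 1 Hz lowpass of the DC signal; human: 0.001-45 Hz band at 200 Hz).
# Channels whose derivative peak stays at or below 1 mV/s are not counted as
# invaded; the stop depth is the depth of the deepest invaded channel.

#' Detect SD onsets per channel
#'
#' Finds, per channel, local maxima of the negative slow-potential derivative
#' exceeding `threshold_mv_per_s`, separated by a refractory period, then
#' groups near-simultaneous candidates across channels into SD events.
#' Events in which no channel exceeds the threshold are discarded.
#'
#' @param rec a DC-coupled `laminar_recording` (rat mode) or `ecog_recording`
#'   / single-channel recording (human mode).
#' @param mode `"rat"` (1 Hz lowpass of the DC signal) or `"human"`
#'   (0.001-45 Hz band).
#' @param threshold_mv_per_s derivative-peak threshold; channels at or below
#'   it are not invaded.
#' @param refractory_s minimum separation between events on one channel.
#' @param group_window_s cross-channel grouping window: candidates within
#'   this window of an event's earliest onset belong to that event.
#' @return list of `sd_event` objects, each with per-channel `onset_s`
#'   (NA where not invaded), `sdprime_peak` (mV/s, all channels),
#'   `earliest_onset_s`, `deepest_onset_s`, `stop_depth_um` and `full_sd`
#'   (laminar recordings only).
#' @export
detect_sd_onsets <- function(rec, mode = c("rat", "human"),
                             threshold_mv_per_s = 1.0, refractory_s = 120,
                             group_window_s = 60) {
  mode <- match.arg(mode)
  if (mode == "rat" && rec$coupling != "DC")
    stopf("rat-mode SD detection requires a DC-coupled recording")
  fs <- rec$fs
  if (rec_duration(rec) < 4) stopf("recording too short for SD detection")
  M <- n_channels(rec)
  cand <- vector("list", M)
  for (m in seq_len(M)) {
    x <- rec$data[m, ]
    filt <- if (mode == "rat") {
      filter_vector(x, fs, 0, 1)
    } else {
      filter_vector(x, fs, 0.001, min(45, fs / 2 * 0.98))
    }
    # negative-going shift => positive peak of the negative derivative
    d <- -c(diff(filt)[1], diff(filt, lag = 2) / 2, diff(filt)[length(filt) - 1]) * fs
    pk <- local_maxima(d)
    # exclude the filter settling margin at the record edges (the 1 Hz
    # corner settles within ~2 s)
    guard <- as.integer(2 * fs)
    pk <- pk[pk > guard & pk <= length(d) - guard]
    pk <- pk[d[pk] > threshold_mv_per_s]
    if (length(pk) > 0) {
      keep <- enforce_separation((pk - 1) / fs, d[pk], refractory_s)
      pk <- pk[keep]
    }
    cand[[m]] <- data.frame(channel = rep(m, length(pk)),
                            time_s = rec$t0 + (pk - 1) / fs, peak = d[pk])
  }
  all_c <- do.call(rbind, cand)
  if (is.null(all_c) || nrow(all_c) == 0) return(list())
  all_c <- all_c[order(all_c$time_s), , drop = FALSE]
  events <- list()
  used <- rep(FALSE, nrow(all_c))
  eid <- 0L
  for (i in seq_len(nrow(all_c))) {
    if (used[i]) next
    grp <- which(!used & all_c$time_s >= all_c$time_s[i] &
                   all_c$time_s <= all_c$time_s[i] + group_window_s)
    # one candidate per channel: strongest derivative peak
    grp <- grp[order(all_c$peak[grp], decreasing = TRUE)]
    grp <- grp[!duplicated(all_c$channel[grp])]
    used[grp] <- TRUE
    eid <- eid + 1L
    onset <- rep(NA_real_, M)
    peaks <- rep(0, M)
    onset[all_c$channel[grp]] <- all_c$time_s[grp]
    peaks[all_c$channel[grp]] <- all_c$peak[grp]
    ev <- structure(list(event_id = eid, onset_s = onset, sdprime_peak = peaks,
                         earliest_onset_s = min(onset, na.rm = TRUE),
                         deepest_onset_s = NA_real_, stop_depth_um = NA_real_,
                         full_sd = NA, threshold_mv_per_s = threshold_mv_per_s),
                    class = "sd_event")
    if (inherits(rec, "laminar_recording") && M > 1) {
      sd_info <- determine_stop_depth(ev, rec, threshold_mv_per_s)
      ev$stop_depth_um <- sd_info$stop_depth_um
      ev$full_sd <- sd_info$full_sd
      ev$invaded <- sd_info$invaded
      ev$deepest_onset_s <- onset[max(which(sd_info$invaded))]
    } else {
      ev$deepest_onset_s <- ev$earliest_onset_s
      ev$invaded <- !is.na(onset)
    }
    events[[eid]] <- ev
  }
  events
}

#' @export
print.sd_event <- function(x, ...) {
  inv <- sum(!is.na(x$onset_s))
  cat(sprintf("<sd_event #%d> %d invaded channel(s), onset %.1f s%s\n",
              x$event_id, inv, x$earliest_onset_s,
              if (!is.na(x$stop_depth_um))
                sprintf(", stop depth %g um%s", x$stop_depth_um,
                        if (isTRUE(x$full_sd)) " (full SD)" else "") else ""))
  invisible(x)
}

#' Determine the vertical stop depth of an SD event
#'
#' The stop depth is the depth of the deepest channel whose derivative peak
#' exceeds the threshold. Raising the threshold can only shrink the invaded
#' set, never deepen the stop.
#'
#' @param event an `sd_event` from [detect_sd_onsets()].
#' @param rec the `laminar_recording` the event was detected on.
#' @param threshold_mv_per_s invasion threshold (mV/s).
#' @return list with `stop_depth_um`, logical `invaded` per channel, and
#'   `full_sd` (TRUE when the deepest probe channel is invaded).
#' @export
determine_stop_depth <- function(event, rec, threshold_mv_per_s = 1.0) {
  invaded <- !is.na(event$onset_s) & event$sdprime_peak > threshold_mv_per_s
  if (!any(invaded)) stopf("event has no invaded channel at threshold %g mV/s",
                           threshold_mv_per_s)
  deepest <- max(which(invaded))
  list(stop_depth_um = rec$depths_um[deepest], invaded = invaded,
       full_sd = deepest == n_channels(rec))
}
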