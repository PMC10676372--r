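# Core data containers: laminar probe recordings, single-channel ECoG,
# intracellular traces and epoch windows. Voltages are in mV with positive
# polarity up; depths are micrometres below the pia, increasing with channel
# index; times are seconds.

#' Laminar multichannel recording
#'
#' Container for a silicon-probe recording: a channels-by-samples voltage
#' matrix with per-channel depths. DC-coupled recordings carry the absolute
#' slow potential so large negative SD shifts are representable.
#'
#' @param data numeric matrix, channels x samples, in mV (positive up).
#' @param depths_um per-channel depth below the pia in micrometres, strictly
#'   increasing with channel index.
#' @param fs sampling rate in Hz.
#' @param t0 recording start time in seconds.
#' @param coupling `"DC"` or `"AC"`.
#' @param meta optional named list of provenance metadata.
#' @return an object of class `laminar_recording`.
#' @export
laminar_recording <- function(data, depths_um, fs, t0 = 0, coupling = c("DC", "AC"),
                              meta = list()) {
  coupling <- match.arg(coupling)
  data <- as.matrix(data)
  if (nrow(data) != length(depths_um))
    stopf("channel count (%d) != length of depths_um (%d)", nrow(data), length(depths_um))
  if (any(diff(depths_um) <= 0)) stopf("depths_um must be strictly increasing")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  structure(list(data = data, depths_um = as.numeric(depths_um), fs = fs,
                 t0 = t0, coupling = coupling, meta = meta),
            class = c("laminar_recording", "sdl_recording"))
}

#' Single-channel ECoG recording
#'
#' Clinical-style single-channel full-band electrocorticogram fragment,
#' nominally 9 minutes at 200 Hz around one SD.
#'
#' @param data numeric vector in mV.
#' @param fs sampling rate in Hz (nominally 200).
#' @param t0 start time in seconds.
#' @param coupling `"DC"` or `"AC"`.
#' @param meta optional named list.
#' @return an object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, fs = 200, t0 = 0, coupling = c("DC", "AC"),
                           meta = list()) {
  coupling <- match.arg(coupling)
  data <- as.numeric(data)
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  structure(list(data = matrix(data, nrow = 1), depths_um = 0, fs = fs, t0 = t0,
                 coupling = coupling, meta = meta),
            class = c("ecog_recording", "sdl_recording"))
}

#' Intracellular membrane-potential trace
#'
#' Whole-cell current-clamp recording. The membrane potential is assumed
#' already corrected for the +15 mV liquid junction potential by the
#' acquisition stage (or the simulator); `junction_corrected` records that.
#'
#' @param em membrane potential in mV.
#' @param fs sampling rate in Hz.
#' @param cell_depth_um depth of the recorded soma below the pia (um).
#' @param t0 start time (s).
#' @param junction_corrected logical flag carried as metadata.
#' @param meta optional named list.
#' @return an object of class `intracellular_trace`.
#' @export
intracellular_trace <- function(em, fs, cell_depth_um, t0 = 0,
                                junction_corrected = TRUE, meta = list()) {
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  structure(list(em = as.numeric(em), fs = fs, cell_depth_um = cell_depth_um,
                 t0 = t0, junction_corrected = junction_corrected, meta = meta),
            class = "intracellular_trace")
}

#' Epoch window relative to a reference event
#'
#' @param start_s,end_s offsets in seconds relative to a reference time;
#'   `end_s` must exceed `start_s`.
#' @return an object of class `epoch_spec`.
#' @export
epoch_spec <- function(start_s, end_s) {
  if (end_s <= start_s) stopf("epoch end (%g) must exceed start (%g)", end_s, start_s)
  structure(list(start_s = start_s, end_s = end_s), class = "epoch_spec")
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$data)) - 1L) / rec$fs

#' @export
print.sdl_recording <- function(x, ...) {
  cat(sprintf("<%s> %d channel(s) x %d samples @ %g Hz, %s-coupled, t0 = %g s\n",
              class(x)[1], n_channels(x), n_samples(x), x$fs, x$coupling, x$t0))
  if (length(x$depths_um) > 1)
    cat(sprintf("  depths: %g-%g um (%g um spacing)\n", min(x$depths_um),
                max(x$depths_um), x$depths_um[2] - x$depths_um[1]))
  invisible(x)
}

#' @export
print.intracellular_trace <- function(x, ...) {
  cat(sprintf("<intracellular_trace> %d samples @ %g Hz, soma at %g um\n",
              length(x$em), x$fs, x$cell_depth_um))
  invisible(x)
}

# Channel of a laminar probe nearest to a given depth; ties -> shallower.
nearest_channel <- function(rec, depth_um) {
  d <- abs(rec$depths_um - depth_um)
  which(d == min(d))[1]
}
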