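# On-disk recording container and event tables.
#
# A recording is stored as a directory holding `meta.json` (fs, t0, coupling,
# depths, free-form metadata) and `data.bin` (little-endian float32,
# channel-major), mirroring an HDF5-style /data, /depths_um, /fs, /meta
# layout. Events travel as plain CSV.

#' Write a recording container
#'
#' @param rec a `laminar_recording` or `ecog_recording`.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(class = class(rec)[1], fs = rec$fs, t0 = rec$t0,
               coupling = rec$coupling, depths_um = rec$depths_um,
               n_channels = n_channels(rec), n_samples = n_samples(rec),
               meta = rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a recording container
#'
#' @param path directory written by [write_recording()].
#' @return the stored recording.
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("not a recording container: %s", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(x) != n) stopf("corrupt container: expected %d samples, got %d", n, length(x))
  data <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  extra <- if (is.list(meta$meta)) meta$meta else list()
  if (identical(meta$class, "ecog_recording")) {
    ecog_recording(data[1, ], fs = meta$fs, t0 = meta$t0, coupling = meta$coupling,
                   meta = extra)
  } else {
    laminar_recording(data, meta$depths_um, fs = meta$fs, t0 = meta$t0,
                      coupling = meta$coupling, meta = extra)
  }
}

#' Write an SD event table
#'
#' Serializes a list of SD events (see [detect_sd_onsets()]) to CSV with one
#' row per invaded channel: `event_id, channel, onset_s,
#' sdprime_peak_mv_per_s, stop_depth_um, label, p_value, ratio`.
#' Classification columns may be `NA` until [classify_sd_change()] results
#' are merged in.
#'
#' @param events list of `sd_event` objects.
#' @param path CSV file path.
#' @return the written data frame, invisibly.
#' @export
write_sd_events <- function(events, path) {
  rows <- lapply(events, function(ev) {
    ch <- which(!is.na(ev$onset_s))
    if (length(ch) == 0L) return(NULL)
    data.frame(event_id = ev$event_id, channel = ch, onset_s = ev$onset_s[ch],
               sdprime_peak_mv_per_s = ev$sdprime_peak[ch],
               stop_depth_um = ev$stop_depth_um %||% NA_real_,
               label = ev$label %||% NA_character_,
               p_value = ev$p_value %||% NA_real_,
               ratio = ev$ratio %||% NA_real_)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(event_id = integer(), channel = integer(),
                                    onset_s = numeric(), sdprime_peak_mv_per_s = numeric(),
                                    stop_depth_um = numeric(), label = character(),
                                    p_value = numeric(), ratio = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read an SD event table written by [write_sd_events()]
#'
#' @param path CSV file path.
#' @return data frame with one row per (event, channel).
#' @export
read_sd_events <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
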