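# End-to-end orchestration: simulate (or load) -> detect -> classify ->
# decompose -> zones, with deterministic summary artifacts.

#' Pipeline configuration
#'
#' Collects every tunable used by the analysis stages with its default:
#' SD' threshold 1 mV/s, significance level 0.05, ICA variance cutoff 1%,
#' the mode-specific epoch windows, and either a simulation request or input
#' paths. The configuration is serialized alongside all outputs.
#'
#' @param simulate list of arguments for [simulate_laminar_session()] (NULL
#'   to read `input` instead).
#' @param input path to a recording container (when not simulating).
#' @param mode `"rat"` or `"human"`.
#' @param sd_threshold_mv_per_s SD' invasion threshold.
#' @param alpha significance level for all tests.
#' @param variance_cutoff ICA component variance cutoff.
#' @param n_pca principal components retained before ICA.
#' @param seed master seed.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), input = NULL,
                            mode = c("rat", "human"),
                            sd_threshold_mv_per_s = 1, alpha = 0.05,
                            variance_cutoff = 0.01, n_pca = 5, seed = 1,
                            outdir = NULL) {
  mode <- match.arg(mode)
  structure(list(simulate = simulate, input = input, mode = mode,
                 sd_threshold_mv_per_s = sd_threshold_mv_per_s, alpha = alpha,
                 variance_cutoff = variance_cutoff, n_pca = n_pca, seed = seed,
                 outdir = outdir),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full SD analysis pipeline
#'
#' simulate/load -> SD detection + stop depth -> per-SD band classification
#' at the top channel -> generator decomposition around the first SD ->
#' (when spike trains are available) MUA change per channel. Writes the
#' event table, classification table, generator profiles and a summary JSON
#' to `outdir` when given; identical config + seed give byte-identical
#' summaries.
#'
#' @param config a [pipeline_config()].
#' @return result bundle: `events`, `classification` (data frame),
#'   `decomposition`, `mua` (or NULL), `summary` (list mirrored in the JSON).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  session <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% config$seed
    session <- do.call(simulate_laminar_session, args)
    rec <- session$lfp
    log_stage("simulate", "%d channels, %.0f s, %d SD plan(s)",
              n_channels(rec), rec_duration(rec), length(args$sd_plans %||% list()))
  } else {
    if (is.null(config$input)) stopf("config needs either a simulation or an input path")
    rec <- tryCatch(read_recording(config$input),
                    error = function(e) stopf("stage input: %s", conditionMessage(e)))
  }

  events <- detect_sd_onsets(rec, mode = if (config$mode == "rat") "rat" else "human",
                             threshold_mv_per_s = config$sd_threshold_mv_per_s)
  log_stage("detect-sd", "%d event(s)", length(events))

  classification <- NULL
  rows <- list()
  for (ev in events) {
    br <- tryCatch(
      band_ratios(rec, ev$earliest_onset_s,
                  mode = if (config$mode == "rat") "rat" else "human",
                  channel = 1, alpha = config$alpha),
      error = function(e) NULL)
    if (is.null(br)) next
    ev_rows <- cbind(data.frame(event_id = ev$event_id,
                                onset_s = ev$earliest_onset_s,
                                stop_depth_um = ev$stop_depth_um), br)
    rows[[length(rows) + 1L]] <- ev_rows
  }
  if (length(rows) > 0) classification <- do.call(rbind, rows)
  log_stage("classify", "%d event(s) classified", length(rows))

  decomp <- NULL
  if (n_channels(rec) >= config$n_pca && length(events) > 0) {
    on1 <- events[[1]]$earliest_onset_s
    ep <- c(max(rec$t0, on1 - 80), min(rec$t0 + rec_duration(rec), on1 + 80))
    if (diff(ep) >= 60) {
      decomp <- tryCatch(
        decompose_generators(rec, epoch_s = ep, n_pca = config$n_pca,
                             min_variance = config$variance_cutoff,
                             seed = config$seed),
        error = function(e) {
          log_stage("decompose", "skipped: %s", conditionMessage(e))
          NULL
        })
    }
  }
  if (!is.null(decomp))
    log_stage("decompose", "%d component(s) kept", decomp$n_components)

  mua <- NULL
  if (!is.null(session) && length(events) > 0) {
    ev1 <- events[[1]]
    if (ev1$earliest_onset_s - 25 >= rec$t0 &&
        ev1$deepest_onset_s + 15 <= rec$t0 + rec_duration(rec)) {
      mua <- mua_change(session$spike_times, ev1)
    }
  }

  summary <- list(
    package = "sdlamina",
    config = list(mode = config$mode, seed = config$seed,
                  sd_threshold_mv_per_s = config$sd_threshold_mv_per_s,
                  alpha = config$alpha, variance_cutoff = config$variance_cutoff,
                  n_pca = config$n_pca),
    n_events = length(events),
    events = lapply(events, function(ev) list(
      event_id = ev$event_id, earliest_onset_s = round(ev$earliest_onset_s, 4),
      stop_depth_um = ev$stop_depth_um, full_sd = ev$full_sd,
      n_invaded = sum(ev$invaded %||% !is.na(ev$onset_s)))),
    labels = if (!is.null(classification))
      classification$label[classification$band == "ac"] else character(0),
    ac_ratios = if (!is.null(classification))
      round(classification$ratio[classification$band == "ac"], 6) else numeric(0),
    n_components = if (!is.null(decomp)) decomp$n_components else 0L,
    variance_fraction = if (!is.null(decomp)) round(decomp$variance_fraction, 6)
      else numeric(0)
  )

  if (!is.null(outdir)) {
    write_sd_events(events, file.path(outdir, "sd_events.csv"))
    if (!is.null(classification))
      utils::write.csv(classification, file.path(outdir, "classification.csv"),
                       row.names = FALSE)
    if (!is.null(decomp)) {
      prof <- data.frame(channel = seq_along(decomp$depths_um),
                         depth_um = decomp$depths_um, decomp$profiles)
      names(prof)[-(1:2)] <- paste0("IC", seq_len(decomp$n_components))
      utils::write.csv(prof, file.path(outdir, "generator_profiles.csv"),
                       row.names = FALSE)
    }
    if (!is.null(mua))
      utils::write.csv(mua, file.path(outdir, "mua_change.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(events = events, classification = classification,
                 decomposition = decomp, mua = mua, summary = summary,
                 recording = rec, session = session))
}

#' Figure-style summary tables from a result bundle
#'
#' Produces the population summaries: the sorted raster (rows = SDs ordered
#' by AC power ratio, columns = time bins of SD-epoch power normalized to
#' the pre-SD mean), the phenotype pie fractions, and the ratio-vs-stop-depth
#' table.
#'
#' @param bundle result of [run_full_analysis()], or a classification data
#'   frame bearing at least `event_id`, `band`, `ratio`, `label`.
#' @param outdir optional directory for CSV artifacts.
#' @return list with `pie_fractions`, `raster` (matrix or NULL) and
#'   `ratio_depth` (data frame or NULL).
#' @export
make_report <- function(bundle, outdir = NULL) {
  cls <- if (is.data.frame(bundle)) bundle else bundle$classification
  if (is.null(cls) || nrow(cls) == 0) stopf("bundle contains no classified SD")
  ac <- cls[cls$band == "ac", , drop = FALSE]
  ac <- ac[order(ac$ratio), , drop = FALSE]
  frac <- c(depression = mean(ac$label == "depression"),
            no_change = mean(ac$label == "no_change"),
            boom = mean(ac$label == "boom"))
  raster <- NULL
  if (!is.data.frame(bundle) && !is.null(bundle$recording) && nrow(ac) > 0) {
    rec <- bundle$recording
    rows <- list()
    for (i in seq_len(nrow(ac))) {
      ep <- tryCatch(epoch_power(rec, ac$onset_s[i],
                                 mode = "rat", band = c(0.5, 45)),
                     error = function(e) NULL)
      if (is.null(ep)) next
      rows[[length(rows) + 1L]] <- ep$sd_powers / mean(ep$pre_powers)
    }
    if (length(rows) > 0) raster <- do.call(rbind, rows)
  }
  ratio_depth <- if (!is.null(ac$stop_depth_um) && any(!is.na(ac$stop_depth_um)))
    data.frame(event_id = ac$event_id, stop_depth_um = ac$stop_depth_um,
               ratio = ac$ratio, label = ac$label) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(label = names(frac), fraction = frac),
                     file.path(outdir, "pie_fractions.csv"), row.names = FALSE)
    if (!is.null(raster))
      utils::write.csv(raster, file.path(outdir, "sorted_raster.csv"),
                       row.names = FALSE)
    if (!is.null(ratio_depth))
      utils::write.csv(ratio_depth, file.path(outdir, "ratio_vs_depth.csv"),
                       row.names = FALSE)
  }
  list(pie_fractions = frac, raster = raster, ratio_depth = ratio_depth)
}

#' Simulate-and-recover batch of single-SD sessions
#'
#' Convenience driver for validation: simulates `n` sessions with one SD
#' each (stop depths drawn uniformly over `stop_range_um`), runs detection
#' and (optionally) top-channel band classification, and tabulates recovery
#' against the planted values.
#'
#' @param n number of SDs.
#' @param seed master seed (each session derives its own stream).
#' @param stop_range_um range of planted stop depths.
#' @param classify also compute top-channel AC/delta/fast power ratios
#'   (slower).
#' @param duration_s session length.
#' @param onset_s planted SD onset at the top channel.
#' @param ... further arguments to [simulate_laminar_session()].
#' @return data frame with one row per SD: planted and recovered onset and
#'   stop depth, and (if requested) `ratio`, `ratio_delta`, `ratio_fast`,
#'   `label`, `p_value`.
#' @export
sd_recovery_batch <- function(n, seed = 1, stop_range_um = c(400, 1600),
                              classify = FALSE, duration_s = 180, onset_s = 70,
                              ...) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sub_seed(seed, i)
    stop_i <- with_seed(si, stats::runif(1, stop_range_um[1], stop_range_um[2]))
    stop_i <- round(stop_i / 10) * 10
    plan <- sd_plan(onset_top_s = onset_s, stop_depth_um = stop_i)
    ses <- simulate_laminar_session(duration_s = duration_s,
                                    sd_plans = list(plan),
                                    seed = si + 1L, ...)
    evs <- detect_sd_onsets(ses$lfp, "rat")
    row <- data.frame(planted_stop_um = stop_i, planted_onset_s = onset_s,
                      detected = length(evs) > 0,
                      detected_stop_um = NA_real_, detected_onset_s = NA_real_,
                      onset_error_s = NA_real_, stop_error_um = NA_real_,
                      ratio = NA_real_, ratio_delta = NA_real_,
                      ratio_fast = NA_real_, label = NA_character_,
                      p_value = NA_real_)
    if (length(evs) > 0) {
      ev <- evs[[1]]
      row$detected_stop_um <- ev$stop_depth_um
      row$detected_onset_s <- ev$onset_s[1]
      row$onset_error_s <- abs(ev$onset_s[1] - onset_s)
      row$stop_error_um <- abs(ev$stop_depth_um - stop_i)
      if (classify) {
        br <- band_ratios(ses$lfp, ev$onset_s[1], mode = "rat", channel = 1)
        row$ratio <- br$ratio[br$band == "ac"]
        row$ratio_delta <- br$ratio[br$band == "delta"]
        row$ratio_fast <- br$ratio[br$band == "fast"]
        row$label <- br$label[br$band == "ac"]
        row$p_value <- br$p_value[br$band == "ac"]
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Per-channel SD/pre activity-change table for zone analysis
#'
#' For one detected SD, computes per channel the delta-band and gamma-band
#' power ratios (multitaper, pre [-40,-10] s vs SD [10,40] s around the
#' earliest onset) and the MUA rate ratio (pre [-25,-10] s before the
#' earliest onset vs [0,15] s after the deepest onset), in the shape
#' [zone_profile()] pools across SDs.
#'
#' @param session a simulated session (or a list with `lfp` and
#'   `spike_times`).
#' @param event an `sd_event` with a stop depth.
#' @param sd_id identifier stored in the output rows.
#' @return data frame: `sd_id`, `depth_um`, `stop_depth_um`, `delta_ratio`,
#'   `gamma_ratio`, `mua_ratio`.
#' @export
zone_change_table <- function(session, event, sd_id = event$event_id) {
  rec <- session$lfp
  mua <- mua_change(session$spike_times, event)
  rows <- lapply(seq_len(n_channels(rec)), function(m) {
    d <- tryCatch(epoch_power(rec, event$earliest_onset_s, mode = "rat",
                              band = c(0.5, 4), channel = m),
                  error = function(e) NULL)
    g <- tryCatch(epoch_power(rec, event$earliest_onset_s, mode = "rat",
                              band = c(30, 45), channel = m),
                  error = function(e) NULL)
    data.frame(sd_id = sd_id, depth_um = rec$depths_um[m],
               stop_depth_um = event$stop_depth_um,
               delta_ratio = if (is.null(d)) NA_real_ else
                 mean(d$sd_powers) / mean(d$pre_powers),
               gamma_ratio = if (is.null(g)) NA_real_ else
                 mean(g$sd_powers) / mean(g$pre_powers),
               mua_ratio = mua$ratio[m])
  })
  do.call(rbind, rows)
}
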