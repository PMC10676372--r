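# Windowed spectral power around SD onsets and the depression / no-change /
# boom classification.
#
# Human mode: band-integrated Welch (Hann-tapered periodogram) power per 5 s
# sliding window, epochs [-120,-90] s (pre-SD) and [10,40] s (SD) around the
# onset. Rat mode: direct Slepian multitaper estimates (0.5 Hz half-
# bandwidth, 3 tapers, 5 s windows), epochs [-40,-10] and [10,40] s. Both
# slide the 5 s window in 1 s steps (the "thirty fragments" per 30 s epoch;
# full windows only, giving 26 values). The SD/pre ratio is the ratio of
# mean window powers; significance is the two-sided Wilcoxon rank-sum test.

.sdl_cache <- new.env(parent = emptyenv())

# Slepian (DPSS) tapers via the classical symmetric tridiagonal eigenproblem.
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(got <- .sdl_cache[[key]])) return(got)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_v
  A[cbind(seq_len(n - 1), 2:n)] <- off_v
  A[cbind(2:n, seq_len(n - 1))] <- off_v
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0 && j %% 2 == 1) tap[, j] <- -tap[, j]
  }
  .sdl_cache[[key]] <- tap
  tap
}

# One-sided band power of one window. taper = "hann" (Welch-style) or a
# matrix of dpss tapers (multitaper mean). Returns integral of the PSD over
# [band1, band2].
window_band_power <- function(x, fs, band, tapers) {
  n <- length(x)
  x <- x - mean(x)
  freqs <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (is.matrix(tapers)) {
    p <- 0
    for (j in seq_len(ncol(tapers))) {
      X <- stats::fft(x * tapers[, j])[seq_along(freqs)]
      p <- p + Mod(X)^2 / fs
    }
    psd <- p / ncol(tapers)
  } else {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    X <- stats::fft(x * w)[seq_along(freqs)]
    psd <- Mod(X)^2 / (fs * sum(w^2))
  }
  psd[-1] <- 2 * psd[-1]
  sum(psd[sel]) * fs / n
}

# Band powers over sliding windows of a vector.
sliding_band_power <- function(x, fs, band, window_s, hop_s, tapers) {
  nwin <- as.integer(round(window_s * fs))
  hop <- max(1L, as.integer(round(hop_s * fs)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  vapply(starts, function(s) window_band_power(x[s:(s + nwin - 1L)], fs, band, tapers),
         numeric(1))
}

# Decimate to target_fs with an anti-aliasing lowpass (integer factor).
decimate_vector <- function(x, fs, target_fs) {
  r <- fs / target_fs
  if (abs(r - round(r)) > 1e-9) stopf("fs %g not an integer multiple of %g", fs, target_fs)
  r <- as.integer(round(r))
  if (r == 1L) return(x)
  y <- filter_vector(x, fs, 0, target_fs * 0.45)
  y[seq(1L, length(y), by = r)]
}

#' Sliding-window band power in pre-SD and SD epochs
#'
#' @param rec a recording; for laminar recordings `channel` selects the trace
#'   (default 1, the top electrode).
#' @param ref_onset_s SD onset (absolute s).
#' @param mode `"human"` (Welch/Hann) or `"rat"` (Slepian multitaper, 0.5 Hz
#'   half-bandwidth, 3 tapers).
#' @param band frequency band in Hz (default full AC band 0.5-45).
#' @param channel channel index for laminar recordings.
#' @param pre_epoch,sd_epoch epoch offsets (s) relative to the onset;
#'   defaults per mode: human pre `[-120,-90]`, rat pre `[-40,-10]`, SD
#'   `[10,40]` for both.
#' @param window_s,hop_s sliding-window length and step.
#' @return list with `pre_powers` and `sd_powers` (per-window band powers,
#'   mV^2) and the epochs used.
#' @export
epoch_power <- function(rec, ref_onset_s, mode = c("human", "rat"),
                        band = c(0.5, 45), channel = 1,
                        pre_epoch = NULL, sd_epoch = c(10, 40),
                        window_s = 5, hop_s = 1) {
  mode <- match.arg(mode)
  if (is.null(pre_epoch)) pre_epoch <- if (mode == "human") c(-120, -90) else c(-40, -10)
  if (band[1] < 0.5 || band[2] > 45)
    message(sprintf("note: band [%g, %g] Hz outside the default 0.5-45 Hz analysis range",
                    band[1], band[2]))
  one_epoch <- function(ep) {
    seg <- epoch_extract(rec, ref_onset_s, epoch_spec(ep[1], ep[2]))
    x <- seg$data[channel, ]
    # remove the epoch's DC offset/drift (an SD epoch sits on a large
    # negative DC plateau) so filter edge transients cannot leak into bands
    tt <- seq_along(x)
    x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
    if (mode == "human") {
      sliding_band_power(x, seg$fs, band, window_s, hop_s, tapers = "hann")
    } else {
      target <- if (seg$fs > 250) 200 else seg$fs
      y <- decimate_vector(x, seg$fs, target)
      nwin <- as.integer(round(window_s * target))
      tap <- dpss_tapers(nwin, nw = 0.5 * window_s, k = 3)
      sliding_band_power(y, target, band, window_s, hop_s, tapers = tap)
    }
  }
  list(pre_powers = one_epoch(pre_epoch), sd_powers = one_epoch(sd_epoch),
       pre_epoch = pre_epoch, sd_epoch = sd_epoch, band = band, mode = mode)
}

# Rank-sum p-value: exact for small untied samples, normal approximation
# with continuity/tie correction otherwise.
ranksum_p <- function(x, y) {
  exact <- length(x) <= 25 && length(y) <= 25 && !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

#' Classify the SD-related change in activity power
#'
#' Labels an SD as `depression`, `no_change` or `boom` from per-window powers
#' in the pre-SD and SD epochs: `no_change` when the two-sided Wilcoxon
#' rank-sum p exceeds 0.05, otherwise `depression`/`boom` according to
#' whether the SD/pre power ratio is below/above 1.
#'
#' @param pre_powers,sd_powers per-window band powers (or the list returned
#'   by [epoch_power()] as the first argument).
#' @param alpha significance level.
#' @param band optional band annotation.
#' @return an `activity_change` object: `ratio`, `p_value`, `label`,
#'   `pre_powers`, `sd_powers`, `band`.
#' @export
classify_sd_change <- function(pre_powers, sd_powers = NULL, alpha = 0.05,
                               band = NULL) {
  if (is.list(pre_powers) && is.null(sd_powers)) {
    band <- band %||% pre_powers$band
    sd_powers <- pre_powers$sd_powers
    pre_powers <- pre_powers$pre_powers
  }
  if (length(pre_powers) < 5 || length(sd_powers) < 5)
    stopf("need >= 5 windows per epoch (%d, %d given)",
          length(pre_powers), length(sd_powers))
  if (all(pre_powers == 0) || all(sd_powers == 0))
    stopf("all-zero powers cannot be classified")
  ratio <- mean(sd_powers) / mean(pre_powers)
  p <- ranksum_p(sd_powers, pre_powers)
  label <- if (p > alpha) "no_change" else if (ratio < 1) "depression" else "boom"
  structure(list(ratio = ratio, p_value = p, label = label,
                 pre_powers = pre_powers, sd_powers = sd_powers, band = band),
            class = "activity_change")
}

#' @export
print.activity_change <- function(x, ...) {
  cat(sprintf("<activity_change> %s: SD/pre ratio %.3g, p = %.3g%s\n", x$label,
              x$ratio, x$p_value,
              if (!is.null(x$band)) sprintf(" [%g-%g Hz]", x$band[1], x$band[2]) else ""))
  invisible(x)
}

#' Band-resolved SD classification
#'
#' Classifies one SD in the standard bands: full AC 0.5-45 Hz, delta 0.5-4,
#' alpha-beta 8-30, gamma 30-45 and fast 8-45 Hz.
#'
#' @inheritParams epoch_power
#' @param alpha significance level.
#' @return data frame with one row per band (`band`, `low_hz`, `high_hz`,
#'   `ratio`, `p_value`, `label`); the `activity_change` objects are attached
#'   as the `"changes"` attribute.
#' @export
band_ratios <- function(rec, ref_onset_s, mode = c("human", "rat"), channel = 1,
                        alpha = 0.05, pre_epoch = NULL, sd_epoch = c(10, 40)) {
  mode <- match.arg(mode)
  bands <- list(ac = c(0.5, 45), delta = c(0.5, 4), alpha_beta = c(8, 30),
                gamma = c(30, 45), fast = c(8, 45))
  changes <- lapply(bands, function(b) {
    ep <- epoch_power(rec, ref_onset_s, mode, band = b, channel = channel,
                      pre_epoch = pre_epoch, sd_epoch = sd_epoch)
    classify_sd_change(ep, alpha = alpha, band = b)
  })
  df <- data.frame(band = names(bands),
                   low_hz = vapply(bands, `[`, numeric(1), 1),
                   high_hz = vapply(bands, `[`, numeric(1), 2),
                   ratio = vapply(changes, `[[`, numeric(1), "ratio"),
                   p_value = vapply(changes, `[[`, numeric(1), "p_value"),
                   label = vapply(changes, `[[`, character(1), "label"),
                   row.names = NULL)
  attr(df, "changes") <- changes
  df
}

#' SD-normalized power spectrum across an SD population
#'
#' Per SD, the mean spectrum of SD-epoch windows divided by the mean
#' spectrum of pre-SD windows; across SDs, the median with quartiles and a
#' per-frequency Wilcoxon signed-rank test of log-ratio against 0. With a
#' single SD the ratios are returned and p is omitted (population test needs
#' at least 6 SDs).
#'
#' @param recordings list of recordings (one per SD).
#' @param onsets_s vector of SD onsets, parallel to `recordings`.
#' @param mode `"human"` or `"rat"`.
#' @param channel channel index.
#' @param fmax upper frequency (Hz) of the reported grid.
#' @param pre_epoch,sd_epoch epoch offsets as in [epoch_power()].
#' @return data frame: `freq_hz`, `median_ratio`, `q1`, `q3`, `p_value`
#'   (NA when fewer than 6 SDs).
#' @export
normalized_spectrum <- function(recordings, onsets_s, mode = c("human", "rat"),
                                channel = 1, fmax = 45,
                                pre_epoch = NULL, sd_epoch = c(10, 40)) {
  mode <- match.arg(mode)
  if (is.null(pre_epoch)) pre_epoch <- if (mode == "human") c(-120, -90) else c(-40, -10)
  window_s <- 5
  spec_of_epoch <- function(rec, onset, ep) {
    seg <- epoch_extract(rec, onset, epoch_spec(ep[1], ep[2]))
    x <- seg$data[channel, ]
    fs <- seg$fs
    if (mode == "rat" && fs > 250) {
      x <- decimate_vector(x, fs, 200)
      fs <- 200
    }
    nwin <- as.integer(round(window_s * fs))
    starts <- seq(1L, length(x) - nwin + 1L, by = as.integer(fs))
    freqs <- (seq_len(nwin %/% 2 + 1) - 1) * fs / nwin
    tap <- if (mode == "rat") dpss_tapers(nwin, 0.5 * window_s, 3) else NULL
    acc <- numeric(length(freqs))
    for (s in starts) {
      w <- x[s:(s + nwin - 1L)]
      w <- w - mean(w)
      if (mode == "rat") {
        p <- 0
        for (j in seq_len(ncol(tap))) p <- p + Mod(stats::fft(w * tap[, j])[seq_along(freqs)])^2
        acc <- acc + p / ncol(tap)
      } else {
        hn <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
        acc <- acc + Mod(stats::fft(w * hn)[seq_along(freqs)])^2
      }
    }
    list(freqs = freqs, psd = acc / length(starts))
  }
  ratios <- NULL
  freqs <- NULL
  for (i in seq_along(recordings)) {
    pre <- spec_of_epoch(recordings[[i]], onsets_s[i], pre_epoch)
    sdp <- spec_of_epoch(recordings[[i]], onsets_s[i], sd_epoch)
    sel <- pre$freqs > 0 & pre$freqs <= fmax
    freqs <- pre$freqs[sel]
    ratios <- rbind(ratios, sdp$psd[sel] / pmax(pre$psd[sel], .Machine$double.xmin))
  }
  n_sd <- nrow(ratios)
  p <- rep(NA_real_, length(freqs))
  if (n_sd >= 6) {
    for (j in seq_along(freqs)) {
      lr <- log(ratios[, j])
      p[j] <- if (all(abs(lr) < 1e-12)) 1 else
        suppressWarnings(stats::wilcox.test(lr, mu = 0, exact = FALSE))$p.value
    }
  }
  data.frame(freq_hz = freqs,
             median_ratio = apply(ratios, 2, stats::median),
             q1 = apply(ratios, 2, stats::quantile, 0.25),
             q3 = apply(ratios, 2, stats::quantile, 0.75),
             p_value = p)
}

#' Relationship between SD stop depth and surface power ratio
#'
#' Spearman correlation (negative when deeper SD penetration suppresses
#' surface activity more) between stop depth and the top-channel power
#' ratio, a Kruskal-Wallis comparison of stop-depth distributions across the
#' depression / no-change / boom labels, and optionally a permutation
#' p-value for the correlation and depth-resolved delta-vs-fast rank-sum
#' tests.
#'
#' @param events data frame with columns `stop_depth_um`, `ratio`, and
#'   optionally `label`, `ratio_delta`, `ratio_fast`.
#' @param n_perm number of permutations for the permutation test of the
#'   Spearman coefficient (0 = skip).
#' @param depth_bin_um bin width for the depth-resolved delta/fast test.
#' @return list with `spearman_r`, `spearman_p`, `perm_p`, `kruskal_p`,
#'   `delta_vs_fast` (per-depth-bin data frame or NULL), `n`.
#' @export
ratio_stopdepth_relation <- function(events, n_perm = 0, depth_bin_um = 300) {
  if (nrow(events) < 10) stopf("need >= 10 SD events (%d given)", nrow(events))
  if (length(unique(events$stop_depth_um)) < 3)
    stopf("need >= 3 distinct stop depths")
  if (stats::sd(events$ratio) == 0) {
    return(list(spearman_r = NA_real_, spearman_p = NA_real_, perm_p = NA_real_,
                kruskal_p = NA_real_, delta_vs_fast = NULL, n = nrow(events),
                note = "constant ratios: correlation undefined"))
  }
  ct <- suppressWarnings(stats::cor.test(events$stop_depth_um, events$ratio,
                                         method = "spearman"))
  perm_p <- NA_real_
  if (n_perm > 0) {
    r_obs <- abs(ct$estimate)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      r_b <- abs(stats::cor(events$stop_depth_um, sample(events$ratio),
                            method = "spearman"))
      if (r_b >= r_obs) cnt <- cnt + 1L
    }
    perm_p <- (cnt + 1) / (n_perm + 1)
  }
  kw <- NA_real_
  if (!is.null(events$label) && length(unique(events$label)) >= 2) {
    kw <- stats::kruskal.test(events$stop_depth_um, factor(events$label))$p.value
  }
  dvf <- NULL
  if (!is.null(events$ratio_delta) && !is.null(events$ratio_fast)) {
    bin <- floor(events$stop_depth_um / depth_bin_um) * depth_bin_um
    dvf <- do.call(rbind, lapply(split(seq_len(nrow(events)), bin), function(idx) {
      if (length(idx) < 3) return(NULL)
      data.frame(depth_bin_um = bin[idx[1]], n = length(idx),
                 p_value = ranksum_p(events$ratio_delta[idx], events$ratio_fast[idx]))
    }))
  }
  list(spearman_r = unname(ct$estimate), spearman_p = ct$p.value, perm_p = perm_p,
       kruskal_p = kw, delta_vs_fast = dvf, n = nrow(events))
}
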