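# Current source density, UP-state / gamma-trough event detection, and
# independent-component decomposition of the laminar field potential into
# spatial generators (profile x time course) with pre/during-SD power
# tracking.

#' Current source density map
#'
#' Second spatial difference of the field potential along the probe axis,
#' smoothed across depth with a triangular kernel of length 3 ((1,2,1)/4,
#' shrunk and renormalized at the probe ends), divided by the squared
#' electrode spacing. Depth-linear potentials map to exactly zero.
#'
#' @param rec a `laminar_recording` with >= 3 uniformly spaced channels.
#' @return a `csd_map`: `csd` ((channels-2) x samples, mV/um^2), `depths_um`
#'   (interior channels), `spacing_um`, `fs`, `t0`.
#' @export
compute_csd <- function(rec) {
  M <- n_channels(rec)
  if (M < 3) stopf("CSD needs >= 3 channels")
  sp <- diff(rec$depths_um)
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1]) stopf("CSD requires uniform channel spacing")
  h <- sp[1]
  u <- rec$data
  d2 <- u[1:(M - 2), , drop = FALSE] - 2 * u[2:(M - 1), , drop = FALSE] +
    u[3:M, , drop = FALSE]
  k <- nrow(d2)
  sm <- d2
  if (k >= 2) {
    sm[1, ] <- (3 * d2[1, ] + d2[2, ]) / 4
    sm[k, ] <- (d2[k - 1, ] + 3 * d2[k, ]) / 4
    if (k >= 3) {
      for (i in 2:(k - 1)) sm[i, ] <- (d2[i - 1, ] + 2 * d2[i, ] + d2[i + 1, ]) / 4
    }
  }
  structure(list(csd = sm / h^2, depths_um = rec$depths_um[2:(M - 1)],
                 spacing_um = h, fs = rec$fs, t0 = rec$t0),
            class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map> %d interior channels x %d samples, %g um spacing\n",
              nrow(x$csd), ncol(x$csd), x$spacing_um))
  invisible(x)
}

# Negative events of a band-filtered trace exceeding 1 STD: local minima
# below -n_std x STD, with a refractory separation.
detect_negative_events <- function(x, fs, t0, band, baseline_s, n_std, refractory_s) {
  f <- filter_vector(x, fs, band[1], min(band[2], fs / 2 * 0.98))
  b1 <- time_to_index(baseline_s[1], t0, fs)
  b2 <- min(length(f), time_to_index(baseline_s[2], t0, fs))
  s <- stats::sd(f[b1:b2])
  if (s == 0) return(numeric(0))
  mins <- local_minima(f)
  mins <- mins[f[mins] < -n_std * s]
  if (length(mins) == 0) return(numeric(0))
  keep <- enforce_separation((mins - 1) / fs, -f[mins], refractory_s)
  t0 + (mins[keep] - 1) / fs
}

#' Detect UP states of delta oscillations
#'
#' UP states are negative events exceeding 1 STD of the 0.5-4 Hz filtered
#' field potential on a deep reference channel; event times are the negative
#' local extrema.
#'
#' @param rec a recording.
#' @param channel_ref reference channel (default: deepest).
#' @param baseline_s window (absolute s) over which the STD is computed;
#'   default the first 60 s. Must be >= 30 s.
#' @param n_std threshold in baseline STDs.
#' @param refractory_s minimum event separation.
#' @return vector of UP-state times (absolute s).
#' @export
detect_up_states <- function(rec, channel_ref = n_channels(rec),
                             baseline_s = NULL, n_std = 1, refractory_s = 0.2) {
  if (rec_duration(rec) < 60) stopf("need >= 60 s of signal for STD estimation")
  baseline_s <- baseline_s %||% c(rec$t0, rec$t0 + min(60, rec_duration(rec)))
  if (diff(baseline_s) < 30) stopf("baseline shorter than 30 s")
  detect_negative_events(rec$data[channel_ref, ], rec$fs, rec$t0, c(0.5, 4),
                         baseline_s, n_std, refractory_s)
}

#' Detect gamma troughs
#'
#' Negative events exceeding 1 STD of the 30-150 Hz filtered field
#' potential.
#'
#' @inheritParams detect_up_states
#' @param channel channel to analyze.
#' @return vector of trough times (absolute s).
#' @export
detect_gamma_troughs <- function(rec, channel = 1, baseline_s = NULL, n_std = 1,
                                 refractory_s = 0.003) {
  if (rec_duration(rec) < 60) stopf("need >= 60 s of signal for STD estimation")
  baseline_s <- baseline_s %||% c(rec$t0, rec$t0 + min(60, rec_duration(rec)))
  if (diff(baseline_s) < 30) stopf("baseline shorter than 30 s")
  detect_negative_events(rec$data[channel, ], rec$fs, rec$t0, c(30, 150),
                         baseline_s, n_std, refractory_s)
}

# Symmetric FastICA with the logcosh contrast on pre-whitened data.
# Z: k x T whitened rows. Returns list(W = k x k orthonormal unmixing or
# NULL, delta = last convergence measure, iters).
fastica_symm <- function(Z, max_iter = 400, tol = 1e-5) {
  k <- nrow(Z)
  Tn <- ncol(Z)
  W <- matrix(stats::rnorm(k * k), k, k)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    gp <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / Tn - diag(gp, k) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, delta = delta, iters = it))
  }
  list(W = NULL, W_last = W, delta = delta, iters = max_iter)
}

#' Decompose a laminar recording into field-potential generators
#'
#' The recorded potentials are modelled as a weighted sum of N source time
#' courses; the decomposition recovers the mixing profiles and sources by
#' PCA reduction to `n_pca` components followed by FastICA. DC drifts are
#' removed beforehand by subtracting a 0.6 s moving-average replica of each
#' channel. Components are ordered by the fraction of signal variance they
#' carry; components below `min_variance` (default the 1% rule) are
#' discarded. Profiles are unit-norm with the largest-magnitude weight
#' positive; sources carry the scale.
#'
#' @param rec a `laminar_recording`.
#' @param epoch_s optional `c(start, end)` absolute seconds (nominally a
#'   160 s epoch containing one SD); default the whole record.
#' @param n_pca number of principal components retained before ICA (5-6).
#' @param min_variance discard components with a variance fraction below
#'   this value.
#' @param seed RNG seed for the ICA initialization; identical seeds give
#'   identical decompositions.
#' @param max_retries additional seeds tried upon non-convergence.
#' @param exclude_s optional list of `c(start, end)` windows (absolute s)
#'   excised from the model fit: SD rise/recovery fronts (whose residual
#'   after DC removal dwarfs the generators) or evoked-potential epochs.
#'   The fitted unmixing is still applied to every sample, so source time
#'   courses cover the full epoch.
#' @return a `generator_decomposition`: `profiles` (channels x N),
#'   `sources` (N x samples), `variance_fraction`, `n_components`,
#'   `depths_um`, `fs`, `t0`, `total_variance`, `discarded_fraction`.
#' @export
decompose_generators <- function(rec, epoch_s = NULL, n_pca = 5,
                                 min_variance = 0.01, seed = 1, max_retries = 5,
                                 exclude_s = NULL) {
  X <- rec$data
  t0 <- rec$t0
  if (!is.null(epoch_s)) {
    seg <- epoch_extract(rec, 0, epoch_spec(epoch_s[1], epoch_s[2]))
    X <- seg$data
    t0 <- seg$t0
  }
  if (ncol(X) < 60 * rec$fs) stopf("epoch must be >= 60 s")
  if (nrow(X) < n_pca) stopf("need at least n_pca = %d channels", n_pca)
  # remove DC/SD drift: subtract a 0.6 s moving-average replica
  w <- as.integer(round(0.6 * rec$fs))
  Xc <- X - t(apply(X, 1, moving_average, w = w))
  Xc <- Xc - rowMeans(Xc)
  Tn <- ncol(Xc)
  fit_idx <- rep(TRUE, Tn)
  for (ex in exclude_s %||% list()) {
    i1 <- max(1L, time_to_index(ex[1], t0, rec$fs))
    i2 <- min(Tn, time_to_index(ex[2], t0, rec$fs))
    if (i1 <= i2) fit_idx[i1:i2] <- FALSE
  }
  if (sum(fit_idx) < 30 * rec$fs)
    stopf("fewer than 30 s of samples left for the fit after exclusion")
  Xf <- Xc[, fit_idx, drop = FALSE]
  Tf <- ncol(Xf)
  total_var <- sum(Xf^2) / Tf
  sv <- svd(Xf, nu = n_pca, nv = 0)
  # degenerate (rank-deficient) data: keep only non-null directions
  n_pca <- min(n_pca, sum(sv$d > 1e-9 * sv$d[1]))
  U <- sv$u[, seq_len(n_pca), drop = FALSE]
  D <- sv$d[seq_len(n_pca)]
  Z <- (t(U) %*% Xf) * (sqrt(Tf) / D)    # k x Tfit whitened
  W <- NULL
  best_W <- NULL
  best_delta <- Inf
  deltas <- numeric(0)
  for (r in 0:max_retries) {
    fit <- with_seed(sub_seed(seed, r), fastica_symm(Z))
    deltas <- c(deltas, fit$delta)
    if (fit$delta < best_delta) {
      best_delta <- fit$delta
      best_W <- fit$W_last %||% fit$W
    }
    if (!is.null(fit$W)) {
      W <- fit$W
      break
    }
  }
  if (is.null(W) && best_delta < 1e-2) {
    # near-converged oscillation between symmetric fixed points (weak or
    # nearly-Gaussian sources): use the best iterate, as is standard
    warning(sprintf("ICA stopped short of full convergence (delta = %.2g); using best iterate",
                    best_delta), call. = FALSE)
    W <- best_W
  }
  if (is.null(W))
    stopf("ICA failed to converge after %d seeds (n_pca = %d, T = %d fit samples; final deltas: %s)",
          max_retries + 1, n_pca, Tf, paste(signif(deltas, 3), collapse = ", "))
  A <- U %*% diag(D / sqrt(Tf), n_pca, n_pca) %*% t(W)   # channel-space mixing
  # apply the fitted unmixing to the full epoch
  Zall <- (t(U) %*% Xc) * (sqrt(Tf) / D)
  S <- W %*% Zall
  comp_var <- colSums(A^2)            # variance carried per component
  vf <- comp_var / total_var
  ord <- order(vf, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  vf <- vf[ord]
  keep <- vf >= min_variance
  discarded <- 1 - sum(vf[keep])
  A <- A[, keep, drop = FALSE]
  S <- S[keep, , drop = FALSE]
  vf <- vf[keep]
  for (j in seq_len(ncol(A))) {
    nrm <- sqrt(sum(A[, j]^2))
    sgn <- sign(A[which.max(abs(A[, j])), j])
    A[, j] <- A[, j] / nrm * sgn
    S[j, ] <- S[j, ] * nrm * sgn
  }
  structure(list(profiles = A, sources = S, variance_fraction = vf,
                 n_components = ncol(A), depths_um = rec$depths_um, fs = rec$fs,
                 t0 = t0, total_variance = total_var,
                 discarded_fraction = discarded, n_pca = n_pca, seed = seed),
            class = "generator_decomposition")
}

#' @export
print.generator_decomposition <- function(x, ...) {
  cat(sprintf("<generator_decomposition> %d component(s) over %d channels (%.1f%% variance kept)\n",
              x$n_components, nrow(x$profiles), 100 * (1 - x$discarded_fraction)))
  invisible(x)
}

#' Per-generator power change between a pre-SD and an SD epoch
#'
#' Ratio of source time-course variance in two 40 s epochs placed before and
#' during the SD, skipping the high-frequency burst heralding the DC shift:
#' epochs must keep >= 5 s clearance from every channel's SD onset.
#'
#' @param decomp a `generator_decomposition`.
#' @param pre_epoch,sd_epoch `c(start, end)` in absolute seconds.
#' @param sd_event optional `sd_event`; when given, epochs within 5 s of any
#'   channel onset raise an error.
#' @return named vector of SD/pre variance ratios, one per component.
#' @export
generator_power_change <- function(decomp, pre_epoch, sd_epoch, sd_event = NULL) {
  if (!is.null(sd_event)) {
    onsets <- sd_event$onset_s[!is.na(sd_event$onset_s)]
    for (ep in list(pre_epoch, sd_epoch)) {
      if (any(onsets >= ep[1] - 5 & onsets <= ep[2] + 5))
        stopf("epoch [%g, %g] s overlaps an SD onset (+/- 5 s guard)", ep[1], ep[2])
    }
  }
  idx <- function(ep) {
    i1 <- time_to_index(ep[1], decomp$t0, decomp$fs)
    i2 <- time_to_index(ep[2], decomp$t0, decomp$fs) - 1L
    if (i1 < 1L || i2 > ncol(decomp$sources))
      stopf("epoch [%g, %g] s outside the decomposed segment", ep[1], ep[2])
    i1:i2
  }
  pre <- idx(pre_epoch)
  sdw <- idx(sd_epoch)
  r <- apply(decomp$sources, 1, function(s) stats::var(s[sdw]) / stats::var(s[pre]))
  names(r) <- paste0("IC", seq_along(r))
  r
}

#' Group generator power ratios by SD stop depth
#'
#' Splits SD events into surface-partial (< 1 mm), intermediate (1-1.5 mm)
#' and full (> 1.5 mm) stop-depth groups and compares each generator's
#' SD/pre power ratios across groups with a Kruskal-Wallis test.
#'
#' @param df data frame with columns `generator`, `stop_depth_um`, `ratio`.
#' @return data frame: per generator, group medians and the Kruskal-Wallis p.
#' @export
generator_group_comparison <- function(df) {
  grp <- cut(df$stop_depth_um, c(-Inf, 1000, 1500, Inf),
             labels = c("lt_1mm", "1_1.5mm", "gt_1.5mm"))
  out <- lapply(split(seq_len(nrow(df)), df$generator), function(idx) {
    g <- grp[idx]
    r <- df$ratio[idx]
    med <- tapply(r, g, stats::median)
    p <- if (length(unique(g[!is.na(g)])) >= 2)
      stats::kruskal.test(r, g)$p.value else NA_real_
    data.frame(generator = df$generator[idx[1]],
               median_lt_1mm = unname(med["lt_1mm"]),
               median_1_1.5mm = unname(med["1_1.5mm"]),
               median_gt_1.5mm = unname(med["gt_1.5mm"]),
               kruskal_p = p)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Align estimated profiles to reference profiles
#'
#' Greedy absolute-correlation matching with sign resolution; utility for
#' validating decompositions against planted generator profiles. A constant
#' (flat) reference profile — the remote-generator signature — has no
#' defined correlation and is instead matched to the flattest remaining
#' estimated profile (minimum coefficient of variation).
#'
#' @param est channels x K estimated profile matrix.
#' @param ref channels x K reference profile matrix.
#' @return list with `order` (est column matched to each ref column), `r`
#'   (absolute correlation per ref column; NA for flat references) and
#'   `cov` (profile coefficient of variation of the matched est column).
#' @export
align_profiles <- function(est, ref) {
  K <- ncol(ref)
  flat_ref <- apply(ref, 2, stats::sd) < 1e-12 * apply(abs(ref), 2, max)
  cors <- suppressWarnings(abs(stats::cor(ref, est)))
  cors[!is.finite(cors)] <- 0
  est_cov <- apply(est, 2, function(p) stats::sd(p) / max(abs(mean(p)), 1e-12))
  ord <- rep(NA_integer_, K)
  r <- rep(NA_real_, K)
  used <- rep(FALSE, ncol(est))
  for (step in seq_len(min(sum(!flat_ref), ncol(est)))) {
    cc <- cors
    cc[, used] <- -1
    cc[flat_ref | !is.na(ord), ] <- -1
    if (max(cc) < 0) break
    i <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    ord[i[1]] <- i[2]
    r[i[1]] <- cors[i[1], i[2]]
    used[i[2]] <- TRUE
  }
  for (k in which(flat_ref)) {
    if (all(used)) break
    cand <- which(!used)
    j <- cand[which.min(est_cov[cand])]
    ord[k] <- j
    used[j] <- TRUE
  }
  list(order = ord, r = r, cov = est_cov[ord])
}
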