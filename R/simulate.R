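# Forward model of a cortical column under spreading depolarization.
#
# The laminar field potential is a weighted sum of source time courses
# (spatial profile x time course per generator) plus SD DC terms and sensor
# noise. Delta-band generators are UP/DOWN event trains; an SD is a
# propagating negative DC shift with a configurable vertical stop depth that
# silences generators whose neurons it invades, leaves deeper generators
# untouched, and creates a narrow gamma-organized excitation band just below
# the stop depth. All planted quantities are returned as ground truth.

#' Default laminar generator set
#'
#' Four field-potential generators mirroring the canonical barrel-cortex
#' decomposition: a dominant mid-layer generator with a polarity reversal at
#' 300-400 um and a broad maximum over layers 4-5 ("Main"), a supragranular
#' generator ("L3"), a deep generator whose far-field limb reaches the
#' surface by volume conduction ("L56"), and a flat extracortical source
#' ("Remote"). Profiles are normalized to unit maximum absolute weight;
#' `core_depth_um` marks where the generating neurons sit (used by the SD
#' silencing rule; `Inf` = never silenced by a cortical SD).
#'
#' @param depths_um probe channel depths (um below pia).
#' @return list of generator specs (name, profile, gain_mv, core_depth_um,
#'   kind, band).
#' @export
default_generator_set <- function(depths_um = seq(100, 1600, by = 100)) {
  z <- depths_um
  norm1 <- function(w) w / max(abs(w))
  list(
    list(name = "Main",
         profile = norm1(exp(-((z - 500) / 150)^2) - 0.8 * exp(-((z - 120) / 150)^2)),
         gain_mv = 0.025, core_depth_um = 450, kind = "delta_updown", band = c(0.5, 4)),
    list(name = "L3",
         profile = norm1(exp(-((z - 300) / 120)^2) - 0.45 * exp(-((z - 650) / 150)^2)),
         gain_mv = 0.0125, core_depth_um = 300, kind = "delta_updown", band = c(0.5, 4)),
    list(name = "L56",
         profile = norm1(0.8 * exp(-((z - 100) / 500)^2) - exp(-((z - 1500) / 220)^2)),
         gain_mv = 0.0575, core_depth_um = 1450, kind = "delta_updown", band = c(0.5, 4)),
    list(name = "Remote",
         profile = rep(1, length(z)),
         gain_mv = 0.00625, core_depth_um = Inf, kind = "flat_remote", band = c(0.5, 4))
  )
}

#' SD plan: one propagating depolarization wave
#'
#' @param onset_top_s time the wave reaches the shallowest channel (s).
#' @param stop_depth_um deepest cortical level reached; at or beyond the
#'   deepest channel means a full SD.
#' @param vertical_speed_um_per_s top-down propagation speed.
#' @param dc_amplitude_mv DC shift amplitude (negative).
#' @param dc_duration_s time from onset to start of recovery at a channel.
#' @param sdprime_mv_s peak of the negative slow-potential derivative the
#'   fall front should produce (sets the fall time constant).
#' @param presd_burst emit the brief gamma-organized excitation burst at SD
#'   arrival on invaded channels.
#' @param subsd_zone_um vertical extent of the elevated-firing band below the
#'   stop depth.
#' @return list of class `sd_plan`.
#' @export
sd_plan <- function(onset_top_s, stop_depth_um, vertical_speed_um_per_s = 100,
                    dc_amplitude_mv = -20, dc_duration_s = 60, sdprime_mv_s = 4,
                    presd_burst = TRUE, subsd_zone_um = 300) {
  if (dc_amplitude_mv >= 0) stopf("dc_amplitude_mv must be negative")
  structure(list(onset_top_s = onset_top_s, stop_depth_um = stop_depth_um,
                 vertical_speed_um_per_s = vertical_speed_um_per_s,
                 dc_amplitude_mv = dc_amplitude_mv, dc_duration_s = dc_duration_s,
                 sdprime_mv_s = sdprime_mv_s, presd_burst = presd_burst,
                 subsd_zone_um = subsd_zone_um),
            class = "sd_plan")
}

# UP/DOWN event-train source: smoothed rectangular depolarizing envelopes,
# inter-onset intervals drawn so the dominant rhythm sits in 0.5-4 Hz and UP
# events last 150-400 ms. Returns the raw envelope (>= 0, for spike rates),
# the zero-mean unit-variance source, and the event onset times.
make_updown_source <- function(n, fs, t0 = 0) {
  dur_s <- n / fs
  n_ev <- ceiling(dur_s / 0.35) + 4L
  iei <- stats::runif(n_ev, 0.35, 1.1)
  onsets <- cumsum(iei)
  onsets <- onsets[onsets < dur_s - 0.2]
  env <- numeric(n)
  durs <- stats::runif(length(onsets), 0.15, 0.4)
  amps <- pmax(0.3, 1 + 0.25 * stats::rnorm(length(onsets)))
  for (k in seq_along(onsets)) {
    i1 <- max(1L, floor(onsets[k] * fs) + 1L)
    i2 <- min(n, i1 + round(durs[k] * fs))
    env[i1:i2] <- pmax(env[i1:i2], amps[k])
  }
  # 50 ms Gaussian smoothing of the rectangular train
  sg <- max(1L, round(0.05 * fs))
  kk <- stats::dnorm(seq(-4, 4, length.out = 8L * sg + 1L))
  kk <- kk / sum(kk)
  env <- stats::convolve(env, rev(kk), type = "open")
  env <- env[(4L * sg + 1L):(4L * sg + n)]
  src <- env - mean(env)
  s <- stats::sd(src)
  if (s > 0) src <- src / s
  list(env = env, src = src, up_times = t0 + onsets)
}

# DC waveform of an SD at one channel: sigmoidal fall (peak derivative =
# |amp| / (4 tau)), plateau, exponential recovery.
sd_dc_waveform <- function(t, onset, amp, tau_fall, duration, tau_rec = 15) {
  L <- stats::plogis((t - onset) / tau_fall)
  R <- ifelse(t < onset + duration, 1, exp(-(t - onset - duration) / tau_rec))
  amp * L * R
}

# Smooth 0/1 suppression window: 1 outside [start, end], ~0 inside.
suppression_mask <- function(t, start, end, ramp_on = 0.25, ramp_off = 1) {
  1 - stats::plogis((t - start) / ramp_on) * (1 - stats::plogis((t - end) / ramp_off))
}

sd_arrival <- function(plan, depth, top_depth) {
  plan$onset_top_s + (min(depth, plan$stop_depth_um) - top_depth) /
    plan$vertical_speed_um_per_s
}

#' Simulate a laminar recording session with ground truth
#'
#' Builds DC-coupled laminar LFP (generator mixture + SD DC shifts + sensor
#' noise), per-channel spike trains (inhomogeneous Poisson, UP-locked,
#' silenced above the SD stop depth after a brief gamma burst, elevated and
#' gamma-modulated in the sub-SD band, unchanged below), optional wideband
#' extracellular traces for spike-detection work, and the full ground truth.
#'
#' @param duration_s session length (s).
#' @param fs_lfp LFP sampling rate (Hz, >= 1 kHz nominal).
#' @param fs_wideband wideband sampling rate (Hz); must be at least twice the
#'   4 kHz spike-band edge.
#' @param depths_um channel depths.
#' @param generators generator list, see [default_generator_set()].
#' @param sd_plans list of [sd_plan()]s (possibly empty).
#' @param noise_mv sensor noise RMS on the LFP (mV).
#' @param include_fast add localized gamma-band sources tied to each cortical
#'   generator (poorly volume-conducted, silenced with their parent).
#' @param include_local_delta add narrow per-channel local delta sources,
#'   silenced wherever the SD invades or in the sub-SD band.
#' @param deep_gain_during_sd amplitude gain applied to the deep (L56) source
#'   while it is spared during a surface-partial SD (1 = no change); the
#'   effective gain ramps down linearly with stop depth, vanishing at
#'   1.4 mm penetration.
#' @param isoguvacine deep-layer silencing scenario: the deep generator and
#'   deep local sources/spiking are suppressed for the whole session.
#' @param spike_base_rate_hz baseline multi-unit rate per channel.
#' @param subsd_rate_gain firing-rate multiplier in the sub-SD band.
#' @param silenced_rate_factor residual firing-rate fraction on SD-invaded
#'   channels (0 = complete silence).
#' @param wideband_channels channels for which wideband traces are
#'   synthesized (empty = none; spike times are always returned).
#' @param wideband_noise_mv wideband noise RMS (mV).
#' @param sd_noise_gain multiplier on wideband noise while a channel is
#'   depolarized (models the tissue-resistance increase during SD).
#' @param spike_amp_mv spike template amplitude on the wideband trace.
#' @param store_sources keep all source time courses in the ground truth
#'   (memory-heavy; needed for mixing-consistency checks).
#' @param store_envelopes keep per-channel local UP envelopes (needed by
#'   [simulate_intracellular()]).
#' @param store_rates keep the planted per-channel rate functions.
#' @param seed RNG seed; identical configuration + seed gives identical output.
#' @return list with `lfp` (laminar_recording), `wideband` (or NULL),
#'   `spike_times` (list per channel), and `truth` (profiles, sources, plans,
#'   zone labels, planted UP times, rates).
#' @export
simulate_laminar_session <- function(duration_s = 200, fs_lfp = 1000,
                                     fs_wideband = 10000,
                                     depths_um = seq(100, 1600, by = 100),
                                     generators = default_generator_set(depths_um),
                                     sd_plans = list(), noise_mv = 0.0015,
                                     include_fast = TRUE, include_local_delta = TRUE,
                                     deep_gain_during_sd = sqrt(2), isoguvacine = FALSE,
                                     spike_base_rate_hz = 5, subsd_rate_gain = 3,
                                     silenced_rate_factor = 0.02,
                                     wideband_channels = integer(0),
                                     wideband_noise_mv = 0.01, sd_noise_gain = 1,
                                     spike_amp_mv = 0.08,
                                     store_sources = FALSE, store_envelopes = FALSE,
                                     store_rates = FALSE, seed = 1) {
  if (length(generators) < 1) stopf("at least one generator required")
  if (fs_wideband < 8000) stopf("fs_wideband (%g) below 2 x 4 kHz spike band", fs_wideband)
  for (p in sd_plans) {
    if (!inherits(p, "sd_plan")) stopf("sd_plans must be a list of sd_plan objects")
    if (p$stop_depth_um < depths_um[1])
      stopf("SD stop depth %g um shallower than shallowest channel (%g um)",
            p$stop_depth_um, depths_um[1])
  }
  with_seed(seed, {
    M <- length(depths_um)
    n <- as.integer(round(duration_s * fs_lfp))
    t <- (seq_len(n) - 1L) / fs_lfp
    top <- depths_um[1]
    max_depth <- depths_um[M]

    src_names <- character(0)
    profiles <- NULL
    sources <- NULL
    up_times <- list()

    add_source <- function(name, profile, series) {
      src_names <<- c(src_names, name)
      profiles <<- cbind(profiles, profile)
      sources <<- rbind(sources, series)
    }

    sd_end <- function(p) p$onset_top_s + p$dc_duration_s + 45

    # ---- delta generators -------------------------------------------------
    gen_env <- list()
    for (g in generators) {
      if (g$kind == "flat_remote") {
        # extracortical volume-conducted activity (distant EEG/ECG-like):
        # delta-band filtered heavy-tailed noise, not an UP/DOWN train
        raw <- stats::rexp(n) * sign(stats::runif(n) - 0.5)
        s <- filter_vector(raw, fs_lfp, 0.5, 4)
        s <- s / stats::sd(s)
        gen_env[[g$name]] <- abs(s)
      } else {
        ud <- make_updown_source(n, fs_lfp)
        gen_env[[g$name]] <- ud$env
        up_times[[g$name]] <- ud$up_times
        s <- ud$src
      }
      if (g$kind != "flat_remote") {
        for (p in sd_plans) {
          silenced <- p$stop_depth_um >= g$core_depth_um - 50
          if (silenced) {
            st <- sd_arrival(p, g$core_depth_um, top)
            s <- s * suppression_mask(t, st, sd_end(p))
          } else if (g$name == "L56" && deep_gain_during_sd != 1) {
            # spared deep generator enhancement, strongest for surface-
            # partial SDs and fading out by 1.4 mm penetration
            ramp <- min(1, max(0, (1400 - p$stop_depth_um) / 1000))
            b <- 1 + (deep_gain_during_sd - 1) * ramp
            w <- 1 - suppression_mask(t, p$onset_top_s, p$onset_top_s + p$dc_duration_s)
            s <- s * (1 + (b - 1) * w)
          }
        }
        if (isoguvacine && g$core_depth_um >= 1200) s <- s * 0.05
      }
      add_source(g$name, g$profile * g$gain_mv, s)
    }

    # ---- localized gamma sources tied to cortical generators --------------
    gamma_f <- c(Main = 38, L3 = 42, L56 = 36)
    if (include_fast) {
      for (g in generators) {
        if (g$kind == "flat_remote") next
        f0 <- gamma_f[[g$name]] %||% 40
        phase <- stats::runif(1, 0, 2 * pi)
        s <- gen_env[[g$name]] * cos(2 * pi * f0 * t + phase)
        for (p in sd_plans) {
          if (p$stop_depth_um >= g$core_depth_um - 50) {
            st <- sd_arrival(p, g$core_depth_um, top)
            s <- s * suppression_mask(t, st, sd_end(p))
          }
        }
        if (isoguvacine && g$core_depth_um >= 1200) s <- s * 0.05
        prof <- exp(-abs(depths_um - g$core_depth_um) / 200)
        add_source(paste0("fast_", g$name), prof / max(prof) * 0.012, s)
      }
    }

    # ---- per-channel local delta sources ----------------------------------
    local_env <- matrix(0, M, n)
    if (include_local_delta) {
      for (m in seq_len(M)) {
        ud <- make_updown_source(n, fs_lfp)
        local_env[m, ] <- ud$env
        up_times[[paste0("local_", m)]] <- ud$up_times
        s <- ud$src
        for (p in sd_plans) {
          if (depths_um[m] <= p$stop_depth_um + p$subsd_zone_um) {
            st <- sd_arrival(p, depths_um[m], top)
            s <- s * suppression_mask(t, st, sd_end(p))
          }
        }
        if (isoguvacine && depths_um[m] >= 1200) s <- s * 0.05
        prof <- exp(-abs(depths_um - depths_um[m]) / 80)
        add_source(paste0("local_", m), prof * 0.00875, s)
      }
    }

    # ---- sub-SD gamma band sources (one per partial SD) -------------------
    sub_gamma_phase <- stats::runif(1, 0, 2 * pi)
    sub_gamma_f <- 40
    for (k in seq_along(sd_plans)) {
      p <- sd_plans[[k]]
      if (!include_fast || p$stop_depth_um >= max_depth) next
      st <- sd_arrival(p, p$stop_depth_um, top)
      env <- stats::plogis((t - st) / 0.5) *
        (1 - stats::plogis((t - p$onset_top_s - p$dc_duration_s) / 2))
      s <- env * cos(2 * pi * sub_gamma_f * t + sub_gamma_phase)
      if (isoguvacine) s <- s * 0.05
      # uniform across the sub-SD band, decaying outside it
      d_out <- pmax(0, p$stop_depth_um - depths_um,
                    depths_um - (p$stop_depth_um + p$subsd_zone_um))
      prof <- exp(-d_out / 80)
      add_source(paste0("subsd_gamma_", k), prof / max(prof) * 0.004, s)
    }

    # ---- mixture, SD DC terms, sensor noise -------------------------------
    lfp <- profiles %*% sources
    dc <- matrix(0, M, n)
    for (p in sd_plans) {
      tau <- abs(p$dc_amplitude_mv) / (4 * p$sdprime_mv_s)
      for (m in seq_len(M)) {
        if (depths_um[m] > p$stop_depth_um) next
        on_m <- sd_arrival(p, depths_um[m], top)
        dc[m, ] <- dc[m, ] + sd_dc_waveform(t, on_m, p$dc_amplitude_mv, tau,
                                            p$dc_duration_s)
      }
    }
    clean <- lfp
    lfp <- lfp + dc
    if (noise_mv > 0) lfp <- lfp + matrix(stats::rnorm(M * n, sd = noise_mv), M, n)

    rec <- laminar_recording(lfp, depths_um, fs_lfp, coupling = "DC",
                             meta = list(simulated = TRUE, seed = seed))

    # ---- spiking ----------------------------------------------------------
    dt <- 1 / fs_lfp
    theta <- 2 * pi * sub_gamma_f * t + sub_gamma_phase
    spike_times <- vector("list", M)
    rates <- if (store_rates) matrix(0, M, n) else NULL
    zone_of <- function(depth, p) {
      if (depth <= p$stop_depth_um) "depressed"
      else if (depth <= p$stop_depth_um + p$subsd_zone_um) "subsd_excited"
      else "unchanged"
    }
    zones <- lapply(sd_plans, function(p) vapply(depths_um, zone_of, "", p = p))
    for (m in seq_len(M)) {
      env_m <- if (include_local_delta) local_env[m, ] else gen_env[[1]]
      mod <- 0.25 + 1.5 * env_m
      lam <- spike_base_rate_hz * mod
      base_mean <- spike_base_rate_hz * mean(mod)
      for (k in seq_along(sd_plans)) {
        p <- sd_plans[[k]]
        z <- zones[[k]][m]
        if (z == "depressed") {
          arr <- sd_arrival(p, depths_um[m], top)
          sil <- t >= arr + 2 & t <= sd_end(p)
          lam[sil] <- silenced_rate_factor * spike_base_rate_hz
          if (p$presd_burst) {
            bw <- t >= arr - 0.5 & t < arr + 2
            lam[bw] <- 4 * spike_base_rate_hz * (1 - 0.7 * cos(theta[bw]))
          }
        } else if (z == "subsd_excited") {
          arr <- sd_arrival(p, p$stop_depth_um, top)
          sw <- t >= arr & t <= p$onset_top_s + p$dc_duration_s
          lam[sw] <- subsd_rate_gain * base_mean * (1 - 0.8 * cos(theta[sw]))
        }
      }
      if (isoguvacine && depths_um[m] >= 1200) lam <- lam * 0.08
      if (store_rates) rates[m, ] <- lam
      hit <- which(stats::runif(n) < lam * dt)
      spike_times[[m]] <- (hit - 1L + stats::runif(length(hit))) * dt
    }

    # ---- optional wideband traces -----------------------------------------
    wideband <- NULL
    if (length(wideband_channels) > 0) {
      nw <- as.integer(round(duration_s * fs_wideband))
      tw <- (seq_len(nw) - 1L) / fs_wideband
      tmpl_t <- seq(0, 1e-3, by = 1 / fs_wideband)
      tmpl <- -sin(pi * pmin(tmpl_t, 5e-4) / 5e-4) +
        0.35 * sin(pi * pmax(tmpl_t - 5e-4, 0) / 5e-4)
      wdata <- matrix(0, length(wideband_channels), nw)
      for (j in seq_along(wideband_channels)) {
        m <- wideband_channels[j]
        nz <- stats::rnorm(nw, sd = wideband_noise_mv)
        if (sd_noise_gain != 1) {
          # SD noise increase is high-frequency weighted (electrode
          # impedance / Johnson noise rises during the SD): add
          # differentiated white noise scaled so the spike-band STD reaches
          # sd_noise_gain x baseline inside the SD window.
          dnz <- c(0, 0, diff(stats::rnorm(nw), differences = 2))
          probe <- spike_band_filter(dnz[seq_len(min(nw, fs_wideband))], fs_wideband)
          base_band <- wideband_noise_mv * sqrt(3750 / (fs_wideband / 2))
          scale_add <- sqrt(max(0, sd_noise_gain^2 - 1)) * base_band /
            stats::sd(probe)
          for (p in sd_plans) {
            if (depths_um[m] > p$stop_depth_um) next
            arr <- sd_arrival(p, depths_um[m], top)
            w <- 1 - suppression_mask(tw, arr, p$onset_top_s + p$dc_duration_s,
                                      ramp_on = 3, ramp_off = 3)
            nz <- nz + dnz * scale_add * w
          }
        }
        x <- nz
        for (st in spike_times[[m]]) {
          i1 <- as.integer(round(st * fs_wideband)) + 1L
          i2 <- i1 + length(tmpl) - 1L
          if (i1 < 1L || i2 > nw) next
          x[i1:i2] <- x[i1:i2] + tmpl * spike_amp_mv * stats::runif(1, 0.85, 1.15)
        }
        wdata[j, ] <- x
      }
      wideband <- laminar_recording(wdata, depths_um[wideband_channels],
                                    fs_wideband, coupling = "AC",
                                    meta = list(simulated = TRUE, wideband = TRUE))
    }

    truth <- list(
      src_names = src_names,
      profiles = if (store_sources) profiles else profiles[, seq_along(generators), drop = FALSE],
      sources = if (store_sources) sources else NULL,
      generator_names = vapply(generators, `[[`, "", "name"),
      sd_plans = sd_plans,
      zones = zones,
      spike_times = spike_times,
      up_times = up_times,
      local_env = if (store_envelopes) local_env else NULL,
      deep_env = if (store_envelopes) gen_env[["L56"]] else NULL,
      rates = rates,
      depths_um = depths_um,
      noise_mv = noise_mv,
      clean_lfp = if (store_sources) clean else NULL,
      seed = seed
    )
    list(lfp = rec, wideband = wideband, spike_times = spike_times, truth = truth)
  })
}

#' Simulate a clinical-style single-channel DC-ECoG fragment
#'
#' One 9-minute fragment around a single SD, built from a surface-negative
#' and a surface-positive delta source plus a negative DC shift. The
#' phenotype is set by which sources are suppressed during the SD: both
#' suppressed = depression; neither = no change; the negative source
#' suppressed and the positive source boosted = boom.
#'
#' @param type `"depression"`, `"no_change"` or `"boom"`.
#' @param fs sampling rate (Hz).
#' @param duration_s fragment length (s), nominally 540.
#' @param onset_s SD onset within the fragment (>= 120 s from the start so
#'   the pre-SD window fits).
#' @param dc_amplitude_mv DC shift amplitude (<= 0; 0 plants no SD).
#' @param sdprime_mv_s target derivative peak of the fall front.
#' @param dc_duration_s shift duration.
#' @param suppression amplitude suppression factor for the depression type
#'   (power is suppressed by its square).
#' @param noise_mv sensor noise RMS.
#' @param seed RNG seed.
#' @return list with `ecog` (an [ecog_recording()]) and `truth` (type,
#'   planted power ratio, onset).
#' @export
simulate_human_ecog <- function(type = c("depression", "no_change", "boom"),
                                fs = 200, duration_s = 540, onset_s = 180,
                                dc_amplitude_mv = -8, sdprime_mv_s = 2.5,
                                dc_duration_s = 90, suppression = 0.32,
                                noise_mv = 0.0005, seed = 1) {
  type <- match.arg(type)
  if (duration_s < 9 * 60) stopf("fragment must be >= 9 minutes")
  if (onset_s < 120) stopf("SD onset must be >= 120 s from fragment start")
  if (dc_amplitude_mv > 0) stopf("dc_amplitude_mv must be <= 0")
  with_seed(seed, {
    n <- as.integer(round(duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    neg <- make_updown_source(n, fs)$src
    pos <- make_updown_source(n, fs)$src
    wn <- -0.012
    wp <- 0.009
    amp_factors <- switch(type,
      depression = c(suppression, suppression),
      no_change = c(1, 1),
      boom = c(0.2, 2.5))
    w <- 1 - suppression_mask(t, onset_s + 2, onset_s + dc_duration_s)
    sn <- neg * (1 + (amp_factors[1] - 1) * w)
    sp <- pos * (1 + (amp_factors[2] - 1) * w)
    x <- wn * sn + wp * sp
    if (dc_amplitude_mv < 0) {
      tau <- abs(dc_amplitude_mv) / (4 * sdprime_mv_s)
      x <- x + sd_dc_waveform(t, onset_s, dc_amplitude_mv, tau, dc_duration_s,
                              tau_rec = 30)
    }
    x <- x + stats::rnorm(n, sd = noise_mv)
    planted_ratio <- (wn^2 * amp_factors[1]^2 + wp^2 * amp_factors[2]^2) /
      (wn^2 + wp^2)
    list(ecog = ecog_recording(x, fs = fs, coupling = "DC",
                               meta = list(simulated = TRUE, type = type)),
         truth = list(type = type, onset_s = onset_s,
                      planted_ratio = planted_ratio,
                      dc_amplitude_mv = dc_amplitude_mv))
  })
}

#' Simulate a whole-cell recording concurrent with a laminar session
#'
#' Builds the true membrane potential of a neuron at a given depth during the
#' session's first SD and the recorded trace (true potential plus the local
#' field potential of the nearest probe channel, so the subtraction
#' correction is testable). Cells invaded by the SD ramp toward the planted
#' peak and stop firing at the planted depolarization-block threshold; cells
#' in the sub-SD band plateau moderately and fire throughout; cells far
#' below barely move.
#'
#' @param session output of [simulate_laminar_session()] (must have been run
#'   with `store_envelopes = TRUE`).
#' @param cell_depth_um soma depth.
#' @param cell_class metadata label (`"RS"`, `"IB"` or `"FS"`); carried, not
#'   modelled.
#' @param rest_mv resting potential.
#' @param peak_invaded_mv planted plateau for invaded cells.
#' @param block_threshold_mv planted AP-inactivation potential.
#' @param peak_subsd_mv planted plateau for sub-SD cells.
#' @param up_amp_mv UP-state depolarization amplitude.
#' @param up_gain_during_sd UP amplitude gain during the SD for cells not
#'   invaded (models the moderate UP reduction under a superficial SD).
#' @param noise_mv recording noise RMS.
#' @param seed RNG seed.
#' @return list with `trace` (recorded [intracellular_trace()]), and `truth`
#'   (true Em, AP times, zone, planted thresholds, nearest channel).
#' @export
simulate_intracellular <- function(session, cell_depth_um, cell_class = "RS",
                                   rest_mv = -65, peak_invaded_mv = -26,
                                   block_threshold_mv = -36, peak_subsd_mv = -47,
                                   up_amp_mv = 8, up_gain_during_sd = 0.7,
                                   noise_mv = 0.3, seed = 1) {
  lfp <- session$lfp
  truth <- session$truth
  if (cell_depth_um < min(truth$depths_um) || cell_depth_um > max(truth$depths_um) + 200)
    stopf("cell depth %g um outside the simulated cortical span", cell_depth_um)
  if (is.null(truth$local_env))
    stopf("session must be simulated with store_envelopes = TRUE")
  fs <- lfp$fs
  with_seed(seed, {
    n <- n_samples(lfp)
    t <- (seq_len(n) - 1L) / fs
    d <- abs(truth$depths_um - cell_depth_um)
    near <- which(d == min(d))[1]
    # the cell's UP drive follows the deep network generator (the same one
    # dominating the L6 LFP), so LFP-detected UP states align with Em
    env <- truth$deep_env %||% truth$local_env[near, ]
    env <- env / max(mean(env), 1e-9) * 0.3   # ~0-1 scale with realistic duty

    plan <- if (length(truth$sd_plans) > 0) truth$sd_plans[[1]] else NULL
    zone <- "unchanged"
    em <- rest_mv + up_amp_mv * env
    rate <- 2 * env / max(env, na.rm = TRUE)
    ap_allowed <- rep(TRUE, n)
    if (!is.null(plan)) {
      zone <- if (cell_depth_um <= plan$stop_depth_um) "depressed"
      else if (cell_depth_um <= plan$stop_depth_um + plan$subsd_zone_um) "subsd_excited"
      else "unchanged"
      top <- truth$depths_um[1]
      sd_on <- plan$onset_top_s
      sd_off <- plan$onset_top_s + plan$dc_duration_s
      if (zone == "depressed") {
        arr <- sd_arrival(plan, cell_depth_um, top)
        ramp <- stats::plogis((t - arr - 4) / 2.5)
        rec_w <- ifelse(t < sd_off, 1, exp(-(t - sd_off) / 10))
        depol <- (peak_invaded_mv - rest_mv) * ramp * rec_w
        em <- rest_mv + up_amp_mv * env * (1 - ramp) + depol
        rate <- rate + 50 * stats::plogis((t - arr) / 0.5) * rec_w
        ap_allowed <- em < block_threshold_mv
      } else if (zone == "subsd_excited") {
        arr <- sd_arrival(plan, plan$stop_depth_um, top)
        ramp <- stats::plogis((t - arr - 2) / 2) *
          (1 - stats::plogis((t - sd_off) / 3))
        depol <- (peak_subsd_mv - rest_mv) * ramp
        em <- rest_mv + up_amp_mv * env * (1 - 0.5 * ramp) + depol
        theta <- 2 * pi * 40 * t
        rate <- rate + 20 * ramp * (1 - 0.8 * cos(theta))
      } else {
        w <- 1 - suppression_mask(t, sd_on, sd_off)
        dist_below <- cell_depth_um - (plan$stop_depth_um + plan$subsd_zone_um)
        small <- max(0, 2.5 * exp(-dist_below / 400))
        em <- rest_mv + small * w +
          up_amp_mv * env * (1 + (up_gain_during_sd - 1) * w)
      }
    }

    dt <- 1 / fs
    hit <- which(stats::runif(n) < rate * dt & ap_allowed)
    # 3 ms refractory
    if (length(hit) > 1) {
      keep <- c(TRUE, diff(hit) > 0.003 * fs)
      hit <- hit[keep]
    }
    ap_times <- (hit - 1L) * dt
    em_true <- em
    ap_len <- round(0.002 * fs)
    ap_shape <- 62 * sin(pi * seq(0, 1, length.out = ap_len + 1))^2
    for (i in hit) {
      i2 <- min(n, i + ap_len)
      em_true[i:i2] <- em_true[i:i2] + ap_shape[seq_len(i2 - i + 1L)]
    }
    recorded <- em_true + lfp$data[near, ] + stats::rnorm(n, sd = noise_mv)
    trace <- intracellular_trace(recorded, fs, cell_depth_um, t0 = lfp$t0,
                                 meta = list(cell_class = cell_class,
                                             nearest_channel = near))
    list(trace = trace,
         truth = list(em_true = em_true, ap_times = ap_times, zone = zone,
                      nearest_channel = near, rest_mv = rest_mv,
                      block_threshold_mv = if (!is.null(plan) && zone == "depressed")
                        block_threshold_mv else NA_real_,
                      planted_peak_mv = switch(zone, depressed = peak_invaded_mv,
                                               subsd_excited = peak_subsd_mv,
                                               rest_mv + 3),
                      sd_plan = plan))
  })
}
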