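# Membrane-potential correction, AP detection, depolarization/block metrics
# and UP-state amplitudes.

test_that("field-potential correction is exact and identity under zero field", {
  fs <- 1000
  tr <- intracellular_trace(rep(-65, 5000), fs, 1100)
  rec0 <- laminar_recording(matrix(0, 16, 5000), seq(100, 1600, 100), fs)
  expect_equal(correct_membrane_potential(tr, rec0)$em, tr$em)
  # nearest-channel rule with shallow tie-breaking
  expect_equal(nearest_channel(rec0, 1100), 11L)
  expect_equal(nearest_channel(rec0, 1150), 11L)
  # misaligned time base
  tr2 <- intracellular_trace(rep(-65, 5000), fs, 1100, t0 = -1)
  expect_error(correct_membrane_potential(tr2, rec0), "misaligned")
})

test_that("AP detection honors threshold and dead time", {
  fs <- 1000
  em <- rep(-65, 20000)
  ap_shape <- 60 * sin(pi * seq(0, 1, length.out = 3))^2
  at <- c(5, 7.2, 9, 9.003, 12)
  for (a in at) {
    i <- round(a * fs)
    em[i:(i + 2)] <- em[i:(i + 2)] + ap_shape
  }
  det <- detect_action_potentials(em, fs)
  expect_length(det, 5)
  expect_true(all(vapply(at, function(a) any(abs(det - a) < 0.005), logical(1))))
  # subthreshold fluctuations are ignored
  set.seed(4)
  em2 <- -65 + cumsum(rnorm(20000, sd = 0.02))
  em2 <- em2 - sdlamina:::moving_average(em2, 2000) - 65
  expect_length(detect_action_potentials(em2, fs), 0)
  expect_error(detect_action_potentials(em, 500), ">= 1 kHz")
})

test_that("block threshold and peak are read off a constructed trajectory", {
  fs <- 1000
  t <- (seq_len(200 * fs) - 1) / fs
  em <- -65 + 40 * plogis((t - 100) / 4) * ifelse(t < 160, 1, exp(-(t - 160) / 10))
  # APs at 40 Hz until the trajectory crosses -36 mV
  cross <- t[min(which(em >= -36))]
  ap_t <- seq(60, cross, by = 0.025)
  emr <- em
  ap_len <- round(0.002 * fs)
  shape <- 62 * sin(pi * seq(0, 1, length.out = ap_len + 1))^2
  for (a in ap_t) {
    i <- round(a * fs) + 1
    emr[i:(i + ap_len)] <- emr[i:(i + ap_len)] + shape
  }
  aps <- detect_action_potentials(emr, fs)
  met <- depolarization_metrics(emr, fs, aps, sd_window = c(90, 160),
                                cell_depth_um = 1100, stop_depth_um = 1600)
  expect_lt(abs(met$block_threshold_mv - (-36)), 2)
  expect_lt(abs(met$peak_em_mv - (-25)), 1)
  expect_false(met$sustained_firing)
  expect_equal(met$distance_to_stop_um, -500)
  # without any SD: no depolarization, no block
  flat <- rep(-65, 100 * fs) + rnorm(100 * fs, sd = 0.1)
  m0 <- depolarization_metrics(flat, fs, numeric(0), sd_window = c(50, 90))
  expect_lt(abs(m0$depol_from_rest_mv), 1)
  expect_true(is.na(m0$block_threshold_mv))
})

test_that("simulated cells recover the planted block and sub-SD plateau", {
  ses <- partial_session()
  plan <- ses$truth$sd_plans[[1]]
  sdw <- c(plan$onset_top_s, plan$onset_top_s + plan$dc_duration_s)
  # invaded cell: ramps to -26, APs cease at the planted -36 mV threshold
  sim_i <- simulate_intracellular(ses, cell_depth_um = 500, seed = 5)
  corr_i <- correct_membrane_potential(sim_i$trace, ses$lfp)
  met_i <- depolarization_metrics(corr_i, ap_times = detect_action_potentials(corr_i),
                                  sd_window = sdw, cell_depth_um = 500,
                                  stop_depth_um = 900)
  expect_lt(abs(met_i$block_threshold_mv - (-36)), 2)
  expect_lt(abs(met_i$peak_em_mv - (-26)), 2)
  expect_false(met_i$sustained_firing)
  # sub-SD cell: plateau near -47 mV, sustained firing, no block
  sim_s <- simulate_intracellular(ses, cell_depth_um = 1100, seed = 6)
  corr_s <- correct_membrane_potential(sim_s$trace, ses$lfp)
  met_s <- depolarization_metrics(corr_s, ap_times = detect_action_potentials(corr_s),
                                  sd_window = sdw, cell_depth_um = 1100,
                                  stop_depth_um = 900)
  expect_lt(abs(met_s$peak_em_mv - (-47)), 2.5)
  expect_true(met_s$sustained_firing)
  expect_true(is.na(met_s$block_threshold_mv))
  # far-below cell barely moves
  sim_f <- simulate_intracellular(ses, cell_depth_um = 1600, seed = 7)
  corr_f <- correct_membrane_potential(sim_f$trace, ses$lfp)
  met_f <- depolarization_metrics(corr_f, ap_times = detect_action_potentials(corr_f),
                                  sd_window = sdw, cell_depth_um = 1600,
                                  stop_depth_um = 900)
  expect_lt(abs(met_f$depol_from_rest_mv), 3)
})

test_that("AP bursts are segmented at the 5 AP/s rate threshold", {
  aps <- c(seq(10, 11, by = 0.05),        # 20 Hz burst, 1 s
           15,                             # isolated
           seq(20, 23, by = 0.15))         # ~6.7 Hz burst, 3 s
  m <- depolarization_metrics(rep(-60, 30000), 1000, aps, sd_window = c(5, 25))
  durs <- sort(m$ap_burst_durations_s)
  expect_length(durs, 2)
  expect_lt(abs(durs[1] - 1), 0.01)
  expect_lt(abs(durs[2] - 3), 0.01)
})

test_that("UP-state amplitudes are exact on plants and attenuate during SDs", {
  fs <- 1000
  n <- 120 * fs
  em <- rep(-65, n)
  trig <- seq(5, 115, by = 1.5)
  for (tt in trig) {
    i <- round(tt * fs)
    em[i:(i + 400)] <- em[i:(i + 400)] + 8 * sin(pi * (0:400) / 400)^2
  }
  ua <- up_state_amplitude(em, fs, trig)
  expect_equal(ua$mean_amplitude_mv, 8, tolerance = 1e-6)
  expect_equal(ua$n_used, length(trig))
  # < 5 triggers: per-event amplitudes only
  ua2 <- up_state_amplitude(em, fs, trig[1:3])
  expect_true(is.na(ua2$mean_amplitude_mv))
  expect_length(ua2$amplitudes_mv, 3)
  # noise only, random triggers: amplitude consistent with zero
  set.seed(5)
  noise <- rnorm(n, sd = 0.5)
  ua3 <- up_state_amplitude(noise, fs, runif(60, 2, 118))
  # averaging-first estimate: peak bias of the 60-epoch average stays near
  # the noise floor, far below any physiological UP amplitude
  expect_lt(ua3$mean_amplitude_mv, 0.4)

  # UP amplitude halved during a superficial SD (deep cell, gain 0.5)
  ses <- fixture("sup_sd", function() {
    s <- simulate_laminar_session(duration_s = 220, store_envelopes = TRUE,
                                  sd_plans = list(sd_plan(90, 400)), seed = 17)
    s
  })
  sim <- simulate_intracellular(ses, cell_depth_um = 1300,
                                up_gain_during_sd = 0.5, noise_mv = 0.05, seed = 3)
  corr <- correct_membrane_potential(sim$trace, ses$lfp)
  ups <- detect_up_states(ses$lfp, channel_ref = 16, baseline_s = c(0, 60))
  pre_t <- ups[ups > 10 & ups < 80]
  sd_t <- ups[ups > 100 & ups < 145]
  a_pre <- up_state_amplitude(corr, up_times = pre_t)
  a_sd <- up_state_amplitude(corr, up_times = sd_t)
  ratio <- a_sd$mean_amplitude_mv / a_pre$mean_amplitude_mv
  expect_lt(abs(ratio - 0.5), 0.15)
})

test_that("depolarization grows with SD penetration relative to the cell", {
  rows <- list()
  k <- 0
  for (stop_i in c(500, 900, 1300, 1600)) {
    ses <- fixture(paste0("fig5f_", stop_i), function() {
      simulate_laminar_session(duration_s = 180, store_envelopes = TRUE,
                               sd_plans = list(sd_plan(70, stop_i)),
                               seed = 300 + stop_i)
    })
    plan <- ses$truth$sd_plans[[1]]
    sdw <- c(plan$onset_top_s, plan$onset_top_s + plan$dc_duration_s)
    for (cd in c(800, 1200, 1600)) {
      k <- k + 1
      sim <- simulate_intracellular(ses, cell_depth_um = cd, seed = k)
      corr <- correct_membrane_potential(sim$trace, ses$lfp)
      met <- depolarization_metrics(corr, ap_times = detect_action_potentials(corr),
                                    sd_window = sdw, cell_depth_um = cd,
                                    stop_depth_um = stop_i)
      rows[[k]] <- data.frame(penetration = stop_i - cd,
                              depol = met$depol_from_rest_mv,
                              n_aps = met$n_aps_sd,
                              burst = if (length(met$ap_burst_durations_s))
                                max(met$ap_burst_durations_s) else 0)
    }
  }
  df <- do.call(rbind, rows)
  ct <- suppressWarnings(cor.test(df$penetration, df$depol, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # sub-block regime: longer bursts accompany stronger depolarization
  sub <- df[df$depol < 25, ]
  expect_gt(suppressWarnings(cor(sub$depol, sub$burst, method = "spearman")), 0)
})
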