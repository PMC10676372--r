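# Spike detection with the adaptive threshold, MUA metrics, zone mapping and
# phase coupling.

test_that("the spike-band filter passes 1 kHz and rejects 50 Hz, zero phase", {
  fs <- 10000
  t <- (seq_len(fs) - 1) / fs
  hi <- sin(2 * pi * 1000 * t)
  lo <- sin(2 * pi * 50 * t)
  mid <- 2000:8000
  y_hi <- spike_band_filter(hi, fs)
  y_lo <- spike_band_filter(lo, fs)
  expect_gt(max(abs(y_hi[mid])), 0.7)
  expect_lt(max(abs(y_lo[mid])), 0.1)
  # symmetric pulse keeps its peak sample (zero-phase reconstruction)
  pulse <- numeric(fs)
  pulse[5000:5020] <- -sin(pi * (0:20) / 20)
  yp <- spike_band_filter(pulse, fs)
  expect_lte(abs(which.min(yp) - which.min(pulse)), 2)
})

wb_session <- function() fixture("wideband", function() {
  ses <- simulate_laminar_session(
    duration_s = 240, fs_wideband = 10000,
    sd_plans = list(sd_plan(onset_top_s = 130, stop_depth_um = 1600)),
    wideband_channels = 3, sd_noise_gain = 2, silenced_rate_factor = 0,
    seed = 42)
  ses$arr3 <- detect_sd_onsets(ses$lfp, "rat")[[1]]$onset_s[3]
  ses
})

test_that("planted spikes at 8x noise are found with high sensitivity and low FDR", {
  ses <- wb_session()
  tr <- detect_spikes(ses$wideband, control_epoch = c(0, 125))[[1]]
  plant <- ses$spike_times[[3]]
  m <- match_events(tr$times_s[tr$times_s < 120], plant[plant < 120], 0.0015)
  expect_gt(m$sensitivity, 0.95)
  expect_lt(m$fdr, 0.05)
  expect_true(all(diff(tr$times_s) > 0))
  expect_true(all(tr$amplitudes_mv < -tr$threshold_mv + 1e-12))
  expect_error(detect_spikes(ses$wideband, control_epoch = c(0, 50)), ">= 100 s")
})

test_that("noise-only detection stays below the analytic level-crossing bound", {
  set.seed(9)
  fs <- 10000
  x <- rnorm(150 * fs, sd = 0.01)
  rec <- laminar_recording(matrix(x, 1), 300, fs, coupling = "AC")
  tr <- detect_spikes(rec, control_epoch = c(0, 150))[[1]]
  # Rice rate of minima below -4 sd for a 250-4000 Hz band
  nu <- sqrt((4000^3 - 250^3) / (3 * (4000 - 250)))
  bound <- nu * exp(-16 / 2)
  expect_lt(length(tr$times_s) / 150, bound)
})

test_that("the adaptive threshold removes SD-noise artifacts that flood a fixed one", {
  ses <- wb_session()
  sdw <- list(c(ses$arr3, ses$arr3 + 60))
  tr_ad <- detect_spikes(ses$wideband, control_epoch = c(0, 125),
                         sd_windows = sdw, adaptive = TRUE)[[1]]
  tr_fx <- detect_spikes(ses$wideband, control_epoch = c(0, 125),
                         sd_windows = sdw, adaptive = FALSE)[[1]]
  inwin <- function(t) sum(t > ses$arr3 + 3 & t < ses$arr3 + 58)
  expect_equal(inwin(tr_ad$times_s), 0L)
  expect_gt(inwin(tr_fx$times_s), 10L)
})

test_that("MUA ratios report planted rate changes with Poisson accuracy", {
  set.seed(3)
  fake_event <- list(earliest_onset_s = 100, deepest_onset_s = 110)
  mk_train <- function(r_pre, r_sd) {
    sort(c(runif(round(r_pre * 60), 40, 100), runif(round(r_sd * 40), 110, 150)))
  }
  trains <- list(mk_train(10, 0.5), mk_train(10, 10), mk_train(10, 30),
                 mk_train(0, 5))
  mc <- mua_change(trains, fake_event)
  expect_lt(abs(mc$ratio[1] - 0.05), 0.05)
  expect_lt(abs(mc$ratio[2] - 1), 0.45)
  expect_lt(abs(mc$ratio[3] - 3), 0.9)
  expect_true(is.na(mc$ratio[4]) && mc$undefined[4])
  expect_lt(mc$p_value[1], 0.05)
})

test_that("burst durations follow the mean + 3 STD rule exactly", {
  # control: alternating 0/2 spikes per 100 ms bin -> known threshold
  ctl <- unlist(lapply(seq(0, 599) / 10, function(b)
    if (round(b * 10) %% 2 == 0) b + c(0.02, 0.06) else numeric(0)))
  thr_rate <- {
    cnt <- rep(c(2, 0), 300) / 0.1
    sm <- sdlamina:::moving_average(cnt, 3L)
    mean(sm) + 3 * sd(sm)
  }
  # SD window: 12 s plateau clearly above threshold, then quiet
  plateau <- unlist(lapply(seq(70, 81.9, by = 0.1), function(b)
    b + seq(0.01, 0.09, by = 0.02)))   # 50 Hz
  spikes <- c(ctl[ctl < 60], plateau)
  d <- burst_duration(spikes, control_epoch = c(0, 60), sd_window = c(65, 95))
  expect_lt(abs(d - 12), 1)
  # constant-rate train: nothing above threshold
  reg <- seq(0.05, 120, by = 0.1)
  expect_equal(burst_duration(reg, c(0, 60), c(65, 95)), 0)
  # excursion below the threshold rate does not count
  sub_rate <- thr_rate * 0.95
  sub <- c(ctl[ctl < 60], unlist(lapply(seq(70, 80, by = 1), function(b)
    b + seq(0, 0.99, length.out = round(sub_rate * 0.1) * 10)[
      seq_len(round(sub_rate))] / round(sub_rate))))
  expect_lte(burst_duration(c(ctl[ctl < 60]), c(0, 60), c(65, 95)), 0)
  expect_equal(burst_duration(numeric(0), c(0, 60), c(65, 95)), 0)
})

test_that("zone labelling follows the significance rules on constructed tables", {
  set.seed(44)
  mk_table <- function(n_sd, stop_fun, ratio_fun) {
    rows <- list()
    for (s in seq_len(n_sd)) {
      stop_i <- stop_fun(s)
      for (d in seq(100, 1600, 100)) {
        r <- ratio_fun(d, stop_i)
        rows[[length(rows) + 1]] <- data.frame(
          sd_id = s, depth_um = d, stop_depth_um = stop_i,
          delta_ratio = r$delta, gamma_ratio = r$gamma, mua_ratio = r$mua)
      }
    }
    do.call(rbind, rows)
  }
  jit <- function(x) x * exp(rnorm(1, 0, 0.15))
  three_zone <- function(d, stop_i) {
    if (d <= stop_i) list(delta = jit(0.6), gamma = jit(0.3), mua = jit(0.05))
    else if (d <= stop_i + 300) list(delta = jit(0.5), gamma = jit(5), mua = jit(3))
    else list(delta = 1, gamma = 1, mua = 1)   # exactly unchanged below
  }
  zt <- mk_table(12, function(s) 400 + (s %% 8) * 100, three_zone)
  zp <- zone_profile(zt)
  expect_equal(attr(zp, "band_top_um"), 100)
  expect_equal(attr(zp, "band_bottom_um"), 300)
  runs <- rle(zp$zone)
  expect_identical(runs$values, c("depressed", "subsd_excited", "unchanged"))
  expect_gt(attr(zp, "peak_mua_increase"), 1)
  # full-SD-only batch: everything invaded is depressed, no excited band
  full_zone <- function(d, stop_i) list(delta = jit(0.05), gamma = jit(0.3),
                                        mua = jit(0.03))
  zf <- zone_profile(mk_table(10, function(s) 1600, full_zone))
  expect_true(all(zf$zone == "depressed"))
  expect_true(is.na(attr(zf, "band_top_um")))
  # no-SD batch: all unchanged
  null_zone <- function(d, stop_i) list(delta = 1, gamma = 1, mua = 1)
  zn <- zone_profile(mk_table(10, function(s) 800, null_zone))
  expect_true(all(zn$zone == "unchanged"))
})

test_that("spikes locked to gamma troughs produce the expected circular statistics", {
  fs <- 1000
  n <- 120 * fs
  t <- (seq_len(n) - 1) / fs
  g <- sin(2 * pi * 60 * t) * 0.02
  rec <- laminar_recording(matrix(g, 1), 500, fs, coupling = "AC")
  troughs <- which(diff(sign(diff(g))) > 0) / fs
  troughs <- troughs[troughs > 1 & troughs < 119]
  pc <- gamma_phase_coupling(troughs[seq(1, length(troughs), by = 7)], rec, 1)
  expect_gt(pc$resultant_length, 0.99)
  expect_lt(pc$rayleigh_p, 1e-6)
  # trough of a sinusoid sits at analytic phase pi
  err <- abs(atan2(sin(pc$mean_direction - pi), cos(pc$mean_direction - pi)))
  expect_lt(err * 180 / pi, 5)
  # fewer than 10 spikes: phases only
  pc2 <- gamma_phase_coupling(troughs[1:5], rec, 1)
  expect_null(pc2$rayleigh_p)
  expect_length(pc2$phases, 5)
})

test_that("circular statistics rotate covariantly and recover planted locking", {
  set.seed(71)
  ph <- r_vonmises(200, mu = 0.8, kappa = 1)
  cm <- circular_mean(ph)
  d <- atan2(sin(cm$mean_direction - 0.8), cos(cm$mean_direction - 0.8))
  expect_lt(abs(d) * 180 / pi, 10)
  rot <- circular_mean(ph + 1.3)
  dd <- atan2(sin(rot$mean_direction - cm$mean_direction - 1.3),
              cos(rot$mean_direction - cm$mean_direction - 1.3))
  expect_lt(abs(dd), 1e-10)
  expect_equal(rot$resultant_length, cm$resultant_length, tolerance = 1e-12)
  expect_equal(rayleigh_test(ph + 1.3)$p_value, rayleigh_test(ph)$p_value,
               tolerance = 1e-12)
  # type-I control at alpha = 0.05 (reduced run; full run in acceptance)
  rej <- 0L
  for (i in 1:300) if (rayleigh_test(runif(500, -pi, pi))$p_value <= 0.05) rej <- rej + 1L
  expect_gt(rej / 300, 0.02)
  expect_lt(rej / 300, 0.09)
})

test_that("sub-SD zone spikes are gamma-locked against the local field", {
  ses <- partial_session()
  ev <- ses$event
  sub_ch <- 11   # 1100 um, inside the planted sub-SD band for a 900 um stop
  st <- ses$spike_times[[sub_ch]]
  st <- st[st > ev$earliest_onset_s + 10 & st < ev$earliest_onset_s + 50]
  pc <- gamma_phase_coupling(st, ses$lfp, sub_ch)
  expect_gt(pc$resultant_length, 0.2)
  expect_lt(pc$rayleigh_p, 1e-4)
})
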