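# Spectral power estimation, the depression/no-change/boom classifier and
# population summaries.

stationary_rec <- function(seed, dur = 200, fs = 1000, band = c(1, 40)) {
  set.seed(seed)
  x <- sdlamina:::filter_vector(rnorm(dur * fs), fs, band[1], band[2])
  laminar_recording(matrix(x, 1), 100, fs, coupling = "DC")
}

test_that("stationary noise gives a unit power ratio in both modes", {
  rec <- stationary_rec(8)
  for (mode in c("human", "rat")) {
    ep <- epoch_power(rec, 130, mode = mode,
                      pre_epoch = if (mode == "human") c(-120, -90) else c(-40, -10))
    r <- mean(ep$sd_powers) / mean(ep$pre_powers)
    expect_gt(r, 0.75)
    expect_lt(r, 1.25)
    expect_length(ep$pre_powers, 26)
  }
})

test_that("amplitude scaling of the SD epoch scales power quadratically", {
  rec <- stationary_rec(9)
  for (fac in c(0.3, 2)) {
    rec2 <- rec
    idx <- (140 * 1000):(175 * 1000)
    rec2$data[1, idx] <- rec2$data[1, idx] * fac
    ep <- epoch_power(rec2, 130, mode = "rat", pre_epoch = c(-40, -10))
    r <- mean(ep$sd_powers) / mean(ep$pre_powers)
    expect_lt(abs(r - fac^2) / fac^2, 0.3)
    cl <- classify_sd_change(ep)
    expect_equal(cl$label, if (fac < 1) "depression" else "boom")
  }
})

test_that("a pure 2 Hz tone concentrates its power in the delta band", {
  fs <- 1000
  t <- (seq_len(200 * fs) - 1) / fs
  rec <- laminar_recording(matrix(sin(2 * pi * 2 * t), 1), 100, fs, coupling = "DC")
  for (mode in c("human", "rat")) {
    d <- epoch_power(rec, 130, mode = mode, band = c(0.5, 4), pre_epoch = c(-40, -10))
    a <- epoch_power(rec, 130, mode = mode, band = c(0.5, 45), pre_epoch = c(-40, -10))
    expect_gt(mean(d$pre_powers) / mean(a$pre_powers), 0.95)
  }
})

test_that("the classifier matches the rank-sum oracle and its invariants", {
  expect_equal(classify_sd_change(1:10 + 0.5, 1:10 + 0.5)$label, "no_change")
  set.seed(2)
  pre <- rnorm(30, 10, 1)
  sdp <- rnorm(30, 1, 0.1)
  cl <- classify_sd_change(pre, sdp)
  expect_equal(cl$label, "depression")
  expect_lt(abs(cl$ratio - 0.1), 0.03)
  expect_equal(cl$p_value,
               wilcox.test(sdp, pre, exact = FALSE, correct = TRUE)$p.value)
  expect_error(classify_sd_change(numeric(0), numeric(0)), ">= 5 windows")
  expect_error(classify_sd_change(rep(0, 10), rep(0, 10)), "all-zero")
  # label always reproduces the sign of (ratio - 1) when significant
  for (s in 1:50) {
    set.seed(s)
    cl <- classify_sd_change(rlnorm(20), rlnorm(20, meanlog = runif(1, -1, 1)))
    if (cl$p_value <= 0.05)
      expect_equal(cl$label, if (cl$ratio < 1) "depression" else "boom")
  }
})

test_that("type-I error of the classifier is calibrated on independent windows", {
  set.seed(77)
  rej <- 0L
  for (i in 1:400) {
    if (classify_sd_change(rlnorm(26), rlnorm(26))$label != "no_change") rej <- rej + 1L
  }
  expect_gt(1 - rej / 400, 0.92)
  expect_lt(1 - rej / 400, 0.98)
})

test_that("classification is invariant to a global amplitude scale", {
  rec <- stationary_rec(10)
  br1 <- band_ratios(rec, 130, mode = "rat", pre_epoch = c(-40, -10))
  rec$data <- rec$data * 7
  br2 <- band_ratios(rec, 130, mode = "rat", pre_epoch = c(-40, -10))
  expect_equal(br1$label, br2$label)
  expect_equal(br1$p_value, br2$p_value, tolerance = 1e-10)
  expect_equal(attr(br2, "changes")$ac$pre_powers,
               attr(br1, "changes")$ac$pre_powers * 49, tolerance = 1e-8)
})

test_that("band-separable suppression is classified band by band", {
  fs <- 1000
  set.seed(12)
  t <- (seq_len(200 * fs) - 1) / fs
  lo <- sdlamina:::filter_vector(rnorm(length(t)), fs, 0.5, 4)
  hi <- sdlamina:::filter_vector(rnorm(length(t)), fs, 8, 45)
  idx <- (140 * fs):(175 * fs)
  sup <- rep(1, length(t))
  sup[idx] <- 0.2
  rec <- laminar_recording(matrix(lo * sup + hi, 1), 100, fs, coupling = "DC")
  br <- band_ratios(rec, 130, mode = "rat", pre_epoch = c(-40, -10))
  expect_equal(br$label[br$band == "delta"], "depression")
  expect_equal(br$label[br$band == "fast"], "no_change")
  # uniform doubling booms every band
  rec2 <- laminar_recording(matrix((lo + hi) * (1 + (2 - 1) * (sup == 0.2)), 1),
                            100, fs, coupling = "DC")
  br2 <- band_ratios(rec2, 130, mode = "rat", pre_epoch = c(-40, -10))
  expect_true(all(br2$label == "boom"))
})

test_that("human and rat estimators agree on stationary band-limited signals", {
  rec <- stationary_rec(13)
  rh <- epoch_power(rec, 130, "human", pre_epoch = c(-120, -90))
  rr <- epoch_power(rec, 130, "rat", pre_epoch = c(-40, -10))
  ratio_h <- mean(rh$sd_powers) / mean(rh$pre_powers)
  ratio_r <- mean(rr$sd_powers) / mean(rr$pre_powers)
  expect_lt(abs(ratio_h - ratio_r) / ratio_r, 0.25)
})

test_that("the normalized population spectrum flags only the suppressed band", {
  fs <- 200
  recs <- list()
  for (s in 1:8) {
    set.seed(400 + s)
    n <- 420 * fs
    t <- (seq_len(n) - 1) / fs
    lo <- sdlamina:::filter_vector(rnorm(n), fs, 0.5, 4)
    hi <- sdlamina:::filter_vector(rnorm(n), fs, 8, 45)
    sup <- rep(1, n)
    sup[(220 * fs):(280 * fs)] <- 0.5   # delta power x 0.25 during "SD"
    recs[[s]] <- ecog_recording(lo * sup + hi, fs = fs, coupling = "DC")
  }
  ns <- normalized_spectrum(recs, rep(210, 8), mode = "human")
  in_delta <- ns$freq_hz >= 1 & ns$freq_hz <= 3.5
  above <- ns$freq_hz >= 10 & ns$freq_hz <= 40
  expect_true(all(ns$median_ratio[in_delta] < 0.6))
  expect_true(all(ns$p_value[in_delta] < 0.05))
  expect_gt(mean(ns$p_value[above] >= 0.05), 0.9)
  # identical epochs: unit ratio everywhere, nothing significant
  ns0 <- normalized_spectrum(recs, rep(100, 8), mode = "human",
                             pre_epoch = c(-90, -60), sd_epoch = c(-90, -60))
  expect_true(all(abs(ns0$median_ratio - 1) < 1e-9))
  expect_true(all(ns0$p_value > 0.9))
  # single SD: ratios but no population p
  ns1 <- normalized_spectrum(recs[1], 210, mode = "human")
  expect_true(all(is.na(ns1$p_value)))
  # independent Welch-style (human) vs multitaper (rat) ratios agree
  ns_rat <- normalized_spectrum(recs, rep(210, 8), mode = "rat",
                                pre_epoch = c(-40, -10))
  common <- ns$freq_hz[in_delta]
  h_i <- approx(ns$freq_hz, ns$median_ratio, common)$y
  r_i <- approx(ns_rat$freq_hz, ns_rat$median_ratio, common)$y
  expect_lt(median(abs(h_i - r_i) / r_i), 0.2)
})

test_that("the stop-depth relation handles signal, permutation and degenerate input", {
  set.seed(55)
  n <- 40
  stops <- runif(n, 400, 1600)
  ratios <- pmax(0.02, 1.4 - stops / 1500 + rnorm(n, sd = 0.15))
  ev <- data.frame(stop_depth_um = stops, ratio = ratios,
                   label = ifelse(ratios < 0.8, "depression",
                                  ifelse(ratios > 1.2, "boom", "no_change")),
                   ratio_delta = ratios, ratio_fast = pmin(1, ratios + 0.3))
  r <- ratio_stopdepth_relation(ev, n_perm = 500)
  expect_lt(r$spearman_r, -0.3)
  expect_lt(r$perm_p, 0.01)
  expect_lt(r$kruskal_p, 0.05)
  expect_s3_class(r$delta_vs_fast, "data.frame")
  expect_error(ratio_stopdepth_relation(ev[1:2, ]), ">= 10")
  const <- ev
  const$ratio <- 1
  expect_true(is.na(ratio_stopdepth_relation(const)$spearman_r))
})
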