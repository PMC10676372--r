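# Shared, lazily-built simulation fixtures (expensive sessions are reused
# across test files).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# One partial SD (stop 900 um) with intracellular support.
partial_session <- function() fixture("partial", function() {
  ses <- simulate_laminar_session(
    duration_s = 200, store_envelopes = TRUE,
    sd_plans = list(sd_plan(onset_top_s = 80, stop_depth_um = 900)), seed = 7)
  ses$event <- detect_sd_onsets(ses$lfp, "rat")[[1]]
  ses
})

# One full SD.
full_session <- function() fixture("full", function() {
  ses <- simulate_laminar_session(
    duration_s = 200,
    sd_plans = list(sd_plan(onset_top_s = 80, stop_depth_um = 1600)), seed = 12)
  ses$event <- detect_sd_onsets(ses$lfp, "rat")[[1]]
  ses
})

# Balanced four-generator mixture used by decomposition benchmarks.
balanced_generators <- function(depths = seq(100, 1600, by = 100)) {
  gens <- default_generator_set(depths)
  gens[[1]]$gain_mv <- 0.025
  gens[[2]]$gain_mv <- 0.02
  gens[[3]]$gain_mv <- 0.03
  gens[[4]]$gain_mv <- 0.02
  gens
}

# Four-generator benchmark mixture at power-SNR 10 for decomposition tests.
ica_bench <- function() fixture("ica_bench", function() {
  gens <- balanced_generators()
  ses <- simulate_laminar_session(duration_s = 300, generators = gens,
                                  include_fast = FALSE, include_local_delta = FALSE,
                                  noise_mv = 0, seed = 21)
  noise_sd <- sqrt(mean(ses$lfp$data^2) / 10)
  set.seed(1)
  ses$lfp$data <- ses$lfp$data +
    matrix(rnorm(length(ses$lfp$data), sd = noise_sd), nrow = 16)
  list(ses = ses, gens = gens)
})

# Brute-force negative-event counter (oracle for UP/gamma detection).
brute_negative_events <- function(x, fs, band, n_std, refractory_s) {
  f <- sdlamina:::filter_vector(x, fs, band[1], min(band[2], fs / 2 * 0.98))
  s <- stats::sd(f)
  idx <- which(f < -n_std * s)
  if (length(idx) == 0) return(0L)
  # count threshold-crossing groups separated by > refractory
  length(which(c(TRUE, diff(idx) > refractory_s * fs)))
}

# Match detected event times to planted times within a tolerance.
match_events <- function(detected, planted, tol) {
  hits <- vapply(planted, function(p) any(abs(detected - p) <= tol), logical(1))
  false_pos <- vapply(detected, function(d) !any(abs(planted - d) <= tol), logical(1))
  list(sensitivity = mean(hits),
       fdr = if (length(detected)) mean(false_pos) else 0)
}
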