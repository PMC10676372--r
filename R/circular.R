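# Circular statistics for spike-gamma phase coupling.

#' Circular mean and resultant length
#'
#' @param phases angles in radians.
#' @return list with `mean_direction` (radians, in (-pi, pi]) and
#'   `resultant_length` in [0, 1].
#' @export
circular_mean <- function(phases) {
  C <- mean(cos(phases))
  S <- mean(sin(phases))
  list(mean_direction = atan2(S, C), resultant_length = sqrt(C^2 + S^2))
}

#' Rayleigh test of circular uniformity
#'
#' Tests phase uniformity against a unimodal alternative; p-value via the
#' standard series approximation.
#'
#' @param phases angles in radians (>= 10 for a meaningful test).
#' @return list with `n`, `resultant_length`, `z` and `p_value`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  R <- circular_mean(phases)$resultant_length
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(n = n, resultant_length = R, z = z, p_value = min(1, p))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used to plant phase-locked spikes in
#' simulations.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 = uniform).
#' @return vector of angles in (-pi, pi].
#' @export
r_vonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

#' Spike-gamma phase coupling
#'
#' Assigns each spike the instantaneous phase of the band-filtered (default
#' 30-150 Hz) field potential at the spike time (Hilbert analytic signal)
#' and summarizes phase locking with the circular mean, resultant length and
#' Rayleigh test. With fewer than 10 spikes the phases are returned but the
#' statistics are omitted.
#'
#' @param spike_times spike times (s) or a `spike_train`.
#' @param rec recording supplying the field potential.
#' @param channel channel index.
#' @param band gamma band (Hz).
#' @return list with `phases`, `n`, and (when n >= 10) `mean_direction`,
#'   `resultant_length`, `rayleigh_p`.
#' @export
gamma_phase_coupling <- function(spike_times, rec, channel = 1, band = c(30, 150)) {
  if (inherits(spike_times, "spike_train")) spike_times <- spike_times$times_s
  f <- filter_vector(rec$data[channel, ], rec$fs, band[1],
                     min(band[2], rec$fs / 2 * 0.98))
  phase <- Arg(analytic_signal(f))
  idx <- time_to_index(spike_times, rec$t0, rec$fs)
  ok <- idx >= 1 & idx <= length(phase)
  phases <- phase[idx[ok]]
  out <- list(phases = phases, n = length(phases))
  if (length(phases) >= 10) {
    cm <- circular_mean(phases)
    out$mean_direction <- cm$mean_direction
    out$resultant_length <- cm$resultant_length
    out$rayleigh_p <- rayleigh_test(phases)$p_value
  }
  out
}
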