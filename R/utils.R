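# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite samples", what)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulations are reproducible without clobbering
#' the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

# Moving average with shrinking windows at the edges (no NA padding).
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict local minima of x.
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n]) + 1L
}

local_maxima <- function(x) local_minima(-x)

# Greedy enforcement of a minimum separation: candidates ranked by strength
# (strongest first) are kept if no stronger kept candidate lies within
# min_sep. Returns kept indices into `times`, sorted by time.
enforce_separation <- function(times, strength, min_sep) {
  if (length(times) == 0L) return(integer(0))
  ord <- order(strength, decreasing = TRUE, times)
  kept_t <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept_t) == 0L || min(abs(kept_t - times[i])) >= min_sep) {
      kept_t <- c(kept_t, times[i])
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# Sample index (1-based) of an absolute time on a recording's grid.
time_to_index <- function(t, t0, fs) as.integer(round((t - t0) * fs)) + 1L

# Analytic signal via FFT (Marple); x must be finite.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
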