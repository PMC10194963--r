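# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`.
# The caller's RNG state is restored afterwards so that seeded generator
# calls do not perturb an enclosing simulation.  seed = NULL means "use the
# current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Columns of 1/f^(exponent)-power ("pink" for exponent = 1) noise, each
# standardized to unit RMS.  Spectral shaping is done in the frequency
# domain; the DC component is removed.
pink_noise <- function(n, m = 1L, exponent = 1) {
  stopifnot(n > 1L, m >= 1L)
  w <- matrix(stats::rnorm(n * m), n, m)
  k <- seq_len(n) - 1L
  fk <- pmin(k, n - k)
  fk[1L] <- Inf # kill DC
  amp <- 1 / fk^(exponent / 2)
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2L, rms, "/")
}

# Gaussian smoothing with a kernel truncated at +/- 3 SD.  Edges are
# renormalized by the kernel mass actually inside the signal, so constants
# are preserved everywhere and interior samples of a line stay exact.
gaussian_smooth <- function(x, sd_samples) {
  n <- length(x)
  if (sd_samples <= 0) return(x)
  h <- max(1L, as.integer(ceiling(3 * sd_samples)))
  if (n <= 2L * h) stop("signal shorter than the smoothing kernel", call. = FALSE)
  k <- stats::dnorm(seq(-h, h), sd = sd_samples)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  (num / den)[(h + 1L):(h + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase filtering with odd-reflection end padding.  signal::filtfilt
# alone leaves large start/end transients (it does no padding); reflecting
# the signal about its endpoints before the forward-backward pass removes
# them and preserves constants exactly.
filtfilt_pad <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  head_ref <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(filt, c(head_ref, x, tail_ref)))
  y[(pad + 1L):(pad + n)]
}
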