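# Optokinetic-nystagmus signal analysis: blink interpolation, zero-phase
# filtering, event-response removal by deconvolution, percent-signal-change
# scaling, slow-phase velocity extraction, zero-crossing switch detection,
# gamma fits to dominance durations and OKN-to-report delay summaries.

#' Construct an oculomotor trace
#'
#' @param samples Position samples (amplitude units); `NA` marks missing
#'   (e.g. blink) samples.
#' @param rate Sampling rate in Hz (eye trackers in this pipeline record at
#'   500 Hz).
#' @param start_time Time of the first sample, seconds.
#' @param blink_events,saccade_events Data frames with `onset`/`offset`
#'   columns in seconds.
#' @return An object of class `oculomotor_trace`.
#' @export
oculomotor_trace <- function(samples, rate = 500, start_time = 0,
                             blink_events = NULL, saccade_events = NULL) {
  stop_if_not_positive(rate, "rate")
  empty <- data.frame(onset = numeric(0), offset = numeric(0))
  blink_events <- blink_events %||% empty
  saccade_events <- saccade_events %||% empty
  span <- start_time + c(0, length(samples) / rate)
  for (ev in list(blink_events, saccade_events)) {
    if (nrow(ev) && (any(ev$onset < span[1] - 1e-9) ||
                     any(ev$offset > span[2] + 1e-9))) {
      stop("event intervals must lie within the trace span", call. = FALSE)
    }
  }
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_time = start_time, blink_events = blink_events,
                 saccade_events = saccade_events),
            class = "oculomotor_trace")
}

trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Interpolate blink gaps
#'
#' For each annotated blink, samples from `pad` ms before its onset to
#' `pad` ms after its offset are replaced by linear interpolation between
#' the surrounding valid samples.  A blink touching a trace boundary is
#' filled by holding the nearest valid value (with a warning).  Any
#' remaining missing samples (un-annotated gaps) are interpolated the same
#' way so that no `NA` survives.
#'
#' @param trace An [oculomotor_trace()].
#' @param pad Padding in ms on each side of a blink.
#' @return The trace with gaps filled.
#' @export
interpolate_blinks <- function(trace, pad = 150) {
  stopifnot(inherits(trace, "oculomotor_trace"), pad >= 0)
  x <- trace$samples
  n <- length(x)
  times <- trace_times(trace)
  mask <- rep(FALSE, n)
  if (nrow(trace$blink_events)) {
    for (b in seq_len(nrow(trace$blink_events))) {
      t0 <- trace$blink_events$onset[b] - pad / 1000
      t1 <- trace$blink_events$offset[b] + pad / 1000
      mask <- mask | (times >= t0 & times <= t1)
    }
  }
  mask <- mask | is.na(x)
  if (!any(mask)) return(trace)
  if (all(mask)) stop("no valid samples to interpolate from", call. = FALSE)
  if (mask[1L] || mask[n]) {
    warning("blink touches a trace boundary; holding nearest valid value")
  }
  good <- which(!mask)
  filled <- stats::approx(times[good], x[good], xout = times,
                          rule = 2)$y # rule 2: hold ends
  x[mask] <- filled[mask]
  trace$samples <- x
  trace
}

#' Zero-phase Butterworth low-pass filter
#'
#' Third-order Butterworth low-pass (default cutoff 10 Hz), applied
#' forward and backward (`signal::filtfilt`) so that crossing times are not
#' biased by filter latency.
#'
#' @param trace An [oculomotor_trace()] without missing samples.
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order Filter order.
#' @return The filtered trace.
#' @export
lowpass_filter <- function(trace, cutoff = 10, order = 3) {
  stopifnot(inherits(trace, "oculomotor_trace"))
  if (cutoff >= trace$rate / 2) {
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  }
  if (anyNA(trace$samples)) {
    stop("trace contains missing samples; run interpolate_blinks() first",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (trace$rate / 2), type = "low")
  pad <- as.integer(ceiling(8 * trace$rate / cutoff))
  trace$samples <- filtfilt_pad(bf, trace$samples, pad)
  trace
}

#' Remove event-locked responses by deconvolution
#'
#' Blink- and saccade-locked mean responses are estimated jointly by
#' least-squares deconvolution: the design matrix holds one shifted event
#' indicator per lag of the response `window`, so overlapping responses are
#' disentangled rather than averaged.  The fitted event responses are then
#' regressed out of the trace.
#'
#' @param trace An [oculomotor_trace()] without missing samples.
#' @param window Response window in seconds, `c(start, end)` relative to
#'   each event onset.
#' @param use_blinks,use_saccades Which annotated event streams to model.
#' @return The cleaned trace; the fitted kernels (one value per lag and
#'   event type) are attached as attribute `"kernels"`.
#' @export
remove_event_responses <- function(trace, window = c(0, 6),
                                   use_blinks = TRUE, use_saccades = TRUE) {
  stopifnot(inherits(trace, "oculomotor_trace"), length(window) == 2L,
            window[2] > window[1])
  if (anyNA(trace$samples)) {
    stop("trace contains missing samples; run interpolate_blinks() first",
         call. = FALSE)
  }
  n <- length(trace$samples)
  rate <- trace$rate
  streams <- list()
  if (use_blinks && nrow(trace$blink_events)) {
    streams$blink <- trace$blink_events$onset
  }
  if (use_saccades && nrow(trace$saccade_events)) {
    streams$saccade <- trace$saccade_events$onset
  }
  if (!length(streams)) return(trace)
  if ((window[2] - window[1]) * rate >= n) {
    stop("deconvolution window is longer than the trace", call. = FALSE)
  }

  lags <- seq(as.integer(round(window[1] * rate)),
              as.integer(round(window[2] * rate)))
  cols <- vector("list", length(streams))
  for (s in seq_along(streams)) {
    onset_idx <- as.integer(round((streams[[s]] - trace$start_time) * rate)) + 1L
    base <- numeric(n)
    keep <- onset_idx >= 1L & onset_idx <= n
    base[onset_idx[keep]] <- 1
    X <- matrix(0, n, length(lags))
    for (j in seq_along(lags)) {
      l <- lags[j]
      if (l >= 0) {
        if (l < n) X[(1L + l):n, j] <- base[1:(n - l)]
      } else {
        X[1:(n + l), j] <- base[(1L - l):n]
      }
    }
    cols[[s]] <- X
  }
  X <- do.call(cbind, cols)
  fit <- stats::lm.fit(cbind(1, X), trace$samples)
  beta <- fit$coefficients[-1L]
  beta[is.na(beta)] <- 0
  kernels <- split(beta, rep(names(streams), each = length(lags)))
  kernels <- lapply(kernels, function(k) {
    names(k) <- NULL
    data.frame(lag_s = lags / rate, response = k)
  })
  trace$samples <- trace$samples - as.numeric(X %*% beta)
  attr(trace, "kernels") <- kernels
  trace
}

#' Convert a trace to percent signal change
#'
#' `100 * (x - m) / m` around the per-block mean `m`.
#'
#' @param trace An [oculomotor_trace()].
#' @param block_mean Block mean; defaults to the trace mean.  Must be
#'   nonzero.
#' @return The rescaled trace.
#' @export
to_percent_signal_change <- function(trace, block_mean = NULL) {
  stopifnot(inherits(trace, "oculomotor_trace"))
  m <- block_mean %||% mean(trace$samples, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    stop("block mean is zero; percent signal change is undefined",
         call. = FALSE)
  }
  trace$samples <- 100 * (trace$samples - m) / m
  trace
}

#' Slow-phase OKN velocity
#'
#' The preprocessed trace is smoothed with a 100-ms Gaussian kernel,
#' differentiated as the difference between neighbouring samples, and
#' smoothed again with the same kernel.  The kernel width is interpreted as
#' full width at half maximum by default (`SD = width / (2 sqrt(2 ln 2))`);
#' set `width_is_fwhm = FALSE` to use it as the SD directly.  Velocity is
#' in amplitude units per sample step (a ramp of `a` units/s gives interior
#' values `a / rate`).  The first/last kernel-width samples are edge-biased
#' and flagged via the `unreliable_ms` field.
#'
#' @param trace An [oculomotor_trace()] without missing samples.
#' @param width_ms Gaussian kernel width in ms.
#' @param width_is_fwhm Interpret `width_ms` as FWHM (default) or as SD.
#' @return An object of class `slow_phase_velocity` with fields `values`,
#'   `rate`, `start_time`, `provenance`, `unreliable_ms`.
#' @export
slow_phase_velocity <- function(trace, width_ms = 100, width_is_fwhm = TRUE) {
  stopifnot(inherits(trace, "oculomotor_trace"))
  if (anyNA(trace$samples)) {
    stop("trace contains missing samples; run interpolate_blinks() first",
         call. = FALSE)
  }
  sd_samples <- width_ms / 1000 * trace$rate
  if (width_is_fwhm) sd_samples <- sd_samples / (2 * sqrt(2 * log(2)))
  n <- length(trace$samples)
  if (n <= 6 * sd_samples + 2) {
    stop("trace shorter than the smoothing kernel", call. = FALSE)
  }
  s1 <- gaussian_smooth(trace$samples, sd_samples)
  v <- diff(s1)
  v <- c(v, v[length(v)]) # edge policy: repeat the last difference
  v <- gaussian_smooth(v, sd_samples)
  structure(list(values = v, rate = trace$rate, start_time = trace$start_time,
                 provenance = list(width_ms = width_ms,
                                   width_is_fwhm = width_is_fwhm,
                                   sd_samples = sd_samples),
                 unreliable_ms = 1000 * 3 * sd_samples / trace$rate),
            class = "slow_phase_velocity")
}

#' Detect perceptual switches as slow-phase velocity zero-crossings
#'
#' Sign changes of the slow-phase velocity are candidate switches.  A
#' crossing is accepted only if the velocity excursion that follows it
#' exceeds `hysteresis` (suppresses chatter around zero) and if it is
#' either at least `min_separation` seconds after the previously accepted
#' crossing or followed by a sign run that itself persists for at least
#' `min_separation` (a persistent reversal is a genuine switch, not
#' bounce; without this rule a rapid double switch would leave the
#' detector's state permanently out of phase).  Accepted directions
#' alternate by construction: a crossing is only accepted when it flips
#' the current confirmed state.  Under the default
#' polarity (stimulus drifting such that the integrated percept pulls the
#' eyes in the negative direction) a positive-to-negative crossing is
#' labelled `to_INT`; use `int_positive = TRUE` for runs with the opposite
#' stimulus drift.
#'
#' @param vel A [slow_phase_velocity()].
#' @param min_separation Debounce interval, seconds.
#' @param hysteresis Velocity threshold; default 10% of the velocity SD.
#' @param int_positive Polarity flag mapping crossing sign to percept.
#' @return Data frame of switch events: `time` (s, linearly interpolated
#'   crossing), `direction`, `source = "okn_crossing"`.
#' @export
detect_switches <- function(vel, min_separation = 0.5, hysteresis = NULL,
                            int_positive = FALSE) {
  stopifnot(inherits(vel, "slow_phase_velocity"))
  v <- vel$values
  n <- length(v)
  empty <- data.frame(time = numeric(0), direction = character(0),
                      source = character(0))
  if (all(v == 0)) {
    warning("all-zero velocity; no switches detected")
    return(empty)
  }
  hysteresis <- hysteresis %||% (0.1 * stats::sd(v))
  sgn <- sign(v)
  # zeros inherit the previous nonzero sign so runs are well defined
  for (i in seq_len(n)) if (sgn[i] == 0) sgn[i] <- if (i > 1L) sgn[i - 1L] else 0
  if (sgn[1L] == 0) {
    first_nz <- which(sgn != 0)[1L]
    sgn[seq_len(first_nz - 1L)] <- sgn[first_nz]
  }
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  peak <- vapply(seq_along(starts),
                 function(k) max(abs(v[starts[k]:ends[k]])), numeric(1))

  state <- 0
  last_t <- -Inf
  out_t <- numeric(0)
  out_dir <- character(0)
  times <- vel$start_time + (seq_len(n) - 1L) / vel$rate
  dt <- 1 / vel$rate
  for (k in seq_along(starts)) {
    if (peak[k] < hysteresis) next
    s <- r$values[k]
    if (state == 0) { state <- s; next }
    if (s == state) next
    i <- starts[k]
    tc <- if (i > 1L && v[i - 1L] != v[i]) {
      times[i - 1L] + dt * v[i - 1L] / (v[i - 1L] - v[i])
    } else times[i]
    run_dur <- (ends[k] - starts[k] + 1L) * dt
    if (tc - last_t < min_separation && run_dur < min_separation) next
    dir_neg <- s < 0
    direction <- if (xor(dir_neg, int_positive)) "to_INT" else "to_DIF"
    out_t <- c(out_t, tc)
    out_dir <- c(out_dir, direction)
    state <- s
    last_t <- tc
  }
  data.frame(time = out_t, direction = out_dir,
             source = rep("okn_crossing", length(out_t)))
}

#' Maximum-likelihood gamma fit with goodness of fit
#'
#' Fits a gamma distribution to dominance durations by maximum likelihood
#' and reports a Kolmogorov-Smirnov goodness-of-fit p value against the
#' fitted distribution.  Near-constant durations make the likelihood
#' surface degenerate; the fit then fails with an informative error.
#'
#' @param durations Positive durations, n >= 20.
#' @return List with `shape`, `scale`, `gof_p` and the underlying
#'   `fitdistrplus` fit object.
#' @export
fit_gamma <- function(durations) {
  if (length(durations) < 20L) stop("need at least 20 durations", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("`durations` must be positive", call. = FALSE)
  }
  fit <- tryCatch(
    fitdistrplus::fitdist(as.numeric(durations), "gamma"),
    error = function(e) stop("gamma fit failed (degenerate durations?): ",
                             conditionMessage(e), call. = FALSE))
  shape <- unname(fit$estimate[["shape"]])
  rate <- unname(fit$estimate[["rate"]])
  ks <- suppressWarnings(stats::ks.test(durations, stats::pgamma,
                                        shape = shape, rate = rate))
  list(shape = shape, scale = 1 / rate, gof_p = unname(ks$p.value), fit = fit)
}

#' Delay between OKN crossings and button presses
#'
#' Pairs each button press with the nearest preceding same-direction OKN
#' crossing within `max_pairing` seconds; unpaired presses are dropped and
#' counted.  When a `subject` column is present, per-subject per-direction
#' mean delays are computed and a paired t test (`to_INT` vs `to_DIF`
#' subject means) is run.
#'
#' @param okn_events,button_events Data frames with `time`, `direction` and
#'   optionally `subject`.
#' @param max_pairing Maximum pairing distance, seconds.
#' @return List with `delays` (one row per paired press), `n_unpaired`,
#'   and, with subjects, `subject_means` and `t_test`.
#' @export
okn_report_delay <- function(okn_events, button_events, max_pairing = 1.5) {
  if (!nrow(okn_events) || !nrow(button_events)) {
    stop("both event streams must be non-empty", call. = FALSE)
  }
  if (!"subject" %in% names(okn_events)) okn_events$subject <- 1L
  if (!"subject" %in% names(button_events)) button_events$subject <- 1L
  rows <- list()
  n_unpaired <- 0L
  for (sub in unique(button_events$subject)) {
    for (dir in unique(button_events$direction)) {
      bp <- button_events[button_events$subject == sub &
                            button_events$direction == dir, , drop = FALSE]
      ok <- okn_events[okn_events$subject == sub &
                         okn_events$direction == dir, , drop = FALSE]
      if (!nrow(bp)) next
      if (!nrow(ok)) { n_unpaired <- n_unpaired + nrow(bp); next }
      ct <- sort(ok$time)
      j <- findInterval(bp$time, ct) # nearest preceding crossing
      delay <- bp$time - ct[pmax(j, 1L)]
      good <- j >= 1L & delay <= max_pairing
      n_unpaired <- n_unpaired + sum(!good)
      if (any(good)) {
        rows[[length(rows) + 1L]] <-
          data.frame(subject = sub, direction = dir,
                     button_time = bp$time[good],
                     okn_time = ct[j[good]], delay = delay[good])
      }
    }
  }
  delays <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = integer(0), direction = character(0),
               button_time = numeric(0), okn_time = numeric(0),
               delay = numeric(0))
  res <- list(delays = delays, n_unpaired = n_unpaired)
  if (nrow(delays)) {
    agg <- stats::aggregate(delay ~ subject + direction, delays, mean)
    wide <- stats::reshape(agg, idvar = "subject", timevar = "direction",
                           direction = "wide")
    res$subject_means <- wide
    if (all(c("delay.to_INT", "delay.to_DIF") %in% names(wide))) {
      ok_rows <- stats::complete.cases(wide)
      if (sum(ok_rows) >= 2L) {
        res$t_test <- stats::t.test(wide$delay.to_INT[ok_rows],
                                    wide$delay.to_DIF[ok_rows], paired = TRUE)
      }
    }
  }
  res
}

#' @export
print.oculomotor_trace <- function(x, ...) {
  cat(sprintf("<oculomotor_trace> %d samples @ %g Hz, %d blinks, %d saccades\n",
              length(x$samples), x$rate, nrow(x$blink_events),
              nrow(x$saccade_events)))
  invisible(x)
}

#' @export
print.slow_phase_velocity <- function(x, ...) {
  cat(sprintf("<slow_phase_velocity> %d samples @ %g Hz (kernel %g ms %s)\n",
              length(x$values), x$rate, x$provenance$width_ms,
              if (x$provenance$width_is_fwhm) "FWHM" else "SD"))
  invisible(x)
}
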