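# Synthetic-session generator: ground-truthed percept schedules, OKN traces
# and multichannel EEG with the statistical structure the downstream
# analyses assume (lagged anterior->posterior coupling gated by the upcoming
# percept, and a low-frequency anterior oscillation that trades off against
# signal complexity).

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-session generator.  Defaults
#' describe the study conditions the package is validated against: 4-minute
#' runs, gamma-distributed dominance durations (shape 3, scale 2 s), OKN at
#' 500 Hz whose slow-phase slope sign tracks the current percept, and 250 Hz
#' EEG in which anterior activity drives posterior activity at a fixed lag,
#' more strongly in the window immediately preceding a switch to the
#' integrated percept, while a 4 Hz anterior oscillation (larger before
#' integrated percepts) lowers anterior signal complexity.
#'
#' @param gamma_shape,gamma_scale Gamma parameters of percept dominance
#'   durations (shape dimensionless, scale seconds).
#' @param session_length Session duration in seconds.
#' @param initial_percept First percept of a session, `"INT"` or `"DIF"`.
#' @param okn_rate Eye-tracker sampling rate (Hz).
#' @param okn_slow_speed Absolute slow-phase slope (amplitude units / s).
#' @param transition_width Width (s) of the sigmoidal slope reversal around
#'   a perceptual switch.
#' @param fast_phase_rate Poisson rate (Hz) of fast-phase resetting saccades.
#' @param blink_rate Poisson rate (Hz) of blinks; blink samples become `NA`.
#' @param eeg_channels Number of EEG channels (a multiple of 4; channels are
#'   split evenly over the front/back/left/right ROI montage).
#' @param eeg_rate EEG sampling rate (Hz).
#' @param coupling_delay Anterior-to-posterior lag in ms (must be a multiple
#'   of the EEG sample period).
#' @param coupling_gain_base,coupling_gain_int,coupling_gain_dif Linear
#'   coupling gain outside modulation windows, and inside the window
#'   preceding a switch to the integrated / differentiated percept.
#' @param lowfreq_hz,lowfreq_amp_int,lowfreq_amp_dif Frequency and
#'   condition-specific amplitude of the anterior low-frequency oscillation.
#' @param premod_window Pre-switch window (ms) during which the modulations
#'   apply.
#' @param noise_sd SD of the background noise (amplitude units).
#' @param report_delay_mean_int,report_delay_mean_dif,report_delay_sd
#'   Gaussian parameters (s) of the OKN-to-button-press report delay.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(gamma_shape = 3, gamma_scale = 2, session_length = 240,
                       initial_percept = c("INT", "DIF"),
                       okn_rate = 500, okn_slow_speed = 1, transition_width = 0.4,
                       fast_phase_rate = 2, blink_rate = 0.2,
                       eeg_channels = 24, eeg_rate = 250,
                       coupling_delay = 100, coupling_gain_base = 0.2,
                       coupling_gain_int = 1, coupling_gain_dif = 0.2,
                       lowfreq_hz = 4, lowfreq_amp_int = 3, lowfreq_amp_dif = 0,
                       premod_window = 600, noise_sd = 1,
                       report_delay_mean_int = 0.5, report_delay_mean_dif = 0.4,
                       report_delay_sd = 0.1,
                       seed = NULL) {
  initial_percept <- match.arg(initial_percept)
  for (nm in c("gamma_shape", "gamma_scale", "session_length", "okn_rate",
               "okn_slow_speed", "transition_width", "eeg_rate",
               "premod_window")) {
    stop_if_not_positive(get(nm), nm)
  }
  stopifnot(noise_sd >= 0, fast_phase_rate >= 0, blink_rate >= 0, coupling_delay >= 0,
            coupling_gain_base >= 0, coupling_gain_int >= 0,
            coupling_gain_dif >= 0, lowfreq_amp_int >= 0, lowfreq_amp_dif >= 0,
            eeg_channels >= 4, eeg_channels %% 4 == 0)
  lag <- coupling_delay * eeg_rate / 1000
  if (abs(lag - round(lag)) > 1e-8) {
    stop("`coupling_delay` must be a multiple of the EEG sample period",
         call. = FALSE)
  }
  structure(
    list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         session_length = session_length, initial_percept = initial_percept,
         okn_rate = okn_rate, okn_slow_speed = okn_slow_speed,
         transition_width = transition_width,
         fast_phase_rate = fast_phase_rate, blink_rate = blink_rate,
         eeg_channels = eeg_channels, eeg_rate = eeg_rate,
         coupling_delay = coupling_delay,
         coupling_gain_base = coupling_gain_base,
         coupling_gain_int = coupling_gain_int,
         coupling_gain_dif = coupling_gain_dif,
         lowfreq_hz = lowfreq_hz, lowfreq_amp_int = lowfreq_amp_int,
         lowfreq_amp_dif = lowfreq_amp_dif,
         premod_window = premod_window, noise_sd = noise_sd,
         report_delay_mean_int = report_delay_mean_int,
         report_delay_mean_dif = report_delay_mean_dif,
         report_delay_sd = report_delay_sd,
         seed = seed),
    class = "sim_config")
}

#' A null configuration: all condition-specific modulations switched off
#'
#' Coupling gains and low-frequency amplitudes are equal across conditions,
#' so every downstream contrast (directed information, complexity, spectral
#' power) is exchangeable between `to_INT` and `to_DIF`.  Used for type-I
#' calibration.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @export
null_config <- function(...) {
  sim_config(coupling_gain_int = 0.2, coupling_gain_dif = 0.2,
             coupling_gain_base = 0.2, lowfreq_amp_int = 0,
             lowfreq_amp_dif = 0, ...)
}

#' Sample percept dominance durations
#'
#' Dominance durations of bistable perception are well described by a gamma
#' distribution; this draws `n` independent gamma variates.
#'
#' @param shape,scale Gamma shape (dimensionless) and scale (seconds).
#' @param n Number of durations.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` durations in seconds.
#' @export
sample_dominance_durations <- function(shape, scale, n, seed = NULL) {
  stop_if_not_positive(shape, "shape")
  stop_if_not_positive(scale, "scale")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  with_seed(seed, stats::rgamma(as.integer(n), shape = shape, scale = scale))
}

#' Build a percept schedule from dominance durations
#'
#' Cumulative sums of the durations become switch times; switch times at or
#' beyond `session_length` are truncated.  Percept labels alternate between
#' `"INT"` and `"DIF"` starting from `initial_percept`.
#'
#' @param durations Positive dominance durations in seconds.
#' @param session_length Session duration in seconds.
#' @param initial_percept Label of the first inter-switch interval.
#' @return A `percept_schedule`: list with `switch_times` (ascending,
#'   seconds), `percepts` (one label per interval, alternating) and
#'   `session_length`.
#' @export
build_schedule <- function(durations, session_length,
                           initial_percept = c("INT", "DIF")) {
  initial_percept <- match.arg(initial_percept)
  if (length(durations) == 0L) stop("`durations` is empty", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("`durations` must be positive", call. = FALSE)
  }
  stop_if_not_positive(session_length, "session_length")
  st <- cumsum(durations)
  st <- st[st < session_length]
  labs <- c("INT", "DIF")
  if (initial_percept == "DIF") labs <- rev(labs)
  percepts <- labs[(seq_len(length(st) + 1L) - 1L) %% 2L + 1L]
  structure(list(switch_times = st, percepts = percepts,
                 session_length = session_length),
            class = "percept_schedule")
}

#' Percept label at given times
#' @param schedule A [build_schedule()] result.
#' @param t Times in seconds.
#' @return Character vector of `"INT"`/`"DIF"` labels.
#' @export
percept_at <- function(schedule, t) {
  schedule$percepts[findInterval(t, schedule$switch_times) + 1L]
}

#' Ground-truth switch events of a schedule
#'
#' @param schedule A `percept_schedule`.
#' @return Data frame with `time` (s), `direction` (`"to_INT"`/`"to_DIF"`,
#'   the upcoming percept) and `source = "truth"`.
#' @export
switch_directions <- function(schedule) {
  k <- length(schedule$switch_times)
  if (k == 0L) {
    return(data.frame(time = numeric(0), direction = character(0),
                      source = character(0)))
  }
  data.frame(time = schedule$switch_times,
             direction = paste0("to_", schedule$percepts[-1L]),
             source = "truth")
}

# Smoothly interpolated slow-phase slope (+/- okn_slow_speed) over a time
# grid; logistic transitions of 10-90% width ~ 0.55 * transition_width.
slow_phase_slope <- function(times, schedule, cfg) {
  pol <- c(INT = -1, DIF = 1) # integrated percept -> negative slow-phase slope
  s0 <- pol[[schedule$percepts[1L]]]
  slope <- rep(s0, length(times))
  tau <- cfg$transition_width / 8
  for (k in seq_along(schedule$switch_times)) {
    target <- pol[[schedule$percepts[k + 1L]]]
    from <- pol[[schedule$percepts[k]]]
    slope <- slope + (target - from) *
      stats::plogis((times - schedule$switch_times[k]) / tau)
  }
  cfg$okn_slow_speed * slope
}

#' Synthesize an optokinetic-nystagmus position trace
#'
#' The slow-phase slope is `-okn_slow_speed` while the integrated percept
#' dominates and `+okn_slow_speed` during the differentiated percept, with
#' smooth sigmoidal reversals around scheduled switches.  Fast-phase resets
#' (Poisson, instantaneous return to baseline) and blink gaps (Poisson
#' onsets, 100-300 ms, samples set to `NA`) are superimposed, plus additive
#' Gaussian noise.
#'
#' @param schedule A `percept_schedule`.
#' @param cfg A [sim_config()].
#' @return An [oculomotor_trace()] with blink and saccade event annotations.
#' @export
synth_okn <- function(schedule, cfg) {
  stopifnot(inherits(schedule, "percept_schedule"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    rate <- cfg$okn_rate
    dt <- 1 / rate
    n <- as.integer(round(schedule$session_length * rate))
    times <- (seq_len(n) - 1L) * dt
    slope <- slow_phase_slope(times, schedule, cfg)
    pos <- cumsum(slope) * dt

    # fast-phase resets: position snaps back to 0 at Poisson event times
    sacc <- data.frame(onset = numeric(0), offset = numeric(0))
    if (cfg$fast_phase_rate > 0) {
      n_sac <- stats::rpois(1L, cfg$fast_phase_rate * schedule$session_length)
      if (n_sac > 0L) {
        t_sac <- sort(stats::runif(n_sac, 0, schedule$session_length))
        idx <- pmin(n, as.integer(floor(t_sac * rate)) + 1L)
        # at each reset the eye snaps back to baseline: subtract the current
        # displacement from all later samples
        for (i in idx) pos[i:n] <- pos[i:n] - pos[i]
        sacc <- data.frame(onset = t_sac, offset = t_sac + dt)
      }
    }

    if (cfg$noise_sd > 0) pos <- pos + stats::rnorm(n, sd = cfg$noise_sd * 0.02)

    blinks <- data.frame(onset = numeric(0), offset = numeric(0))
    if (cfg$blink_rate > 0) {
      n_bl <- stats::rpois(1L, cfg$blink_rate * schedule$session_length)
      if (n_bl > 0L) {
        on <- sort(stats::runif(n_bl, 0, schedule$session_length))
        dur <- stats::runif(n_bl, 0.1, 0.3)
        off <- pmin(on + dur, schedule$session_length)
        for (b in seq_len(n_bl)) {
          i0 <- max(1L, as.integer(floor(on[b] * rate)) + 1L)
          i1 <- min(n, as.integer(ceiling(off[b] * rate)))
          pos[i0:i1] <- NA_real_
        }
        blinks <- data.frame(onset = on, offset = off)
      }
    }

    oculomotor_trace(pos, rate = rate, start_time = 0,
                     blink_events = blinks, saccade_events = sacc)
  })
}

roi_channel_names <- function(n_per_roi) {
  defs <- roi_definitions(n_per_roi)
  unlist(defs, use.names = FALSE)
}

# Condition-gated gain/amplitude time courses over an EEG sample grid.
gated_series <- function(times_s, schedule, cfg, base, val_int, val_dif) {
  g <- rep(base, length(times_s))
  w <- cfg$premod_window / 1000
  for (k in seq_along(schedule$switch_times)) {
    tk <- schedule$switch_times[k]
    val <- if (schedule$percepts[k + 1L] == "INT") val_int else val_dif
    g[times_s >= (tk - w) & times_s <= tk] <- val
  }
  g
}

#' Synthesize a multichannel EEG recording with known information structure
#'
#' Each channel carries 1/f background noise.  Anterior (front-ROI) channels
#' share a white latent source `A(t)`; posterior (back-ROI) channels receive
#' `g(t) * A(t - delay)` where the gain `g` equals `coupling_gain_int`
#' (resp. `_dif`) inside the `premod_window` before a switch to the
#' integrated (resp. differentiated) percept and `coupling_gain_base`
#' elsewhere.  Anterior channels additionally receive a low-frequency
#' oscillation whose amplitude is gated the same way.  Temporal-ROI channels
#' are pure background.
#'
#' @param schedule A `percept_schedule`.
#' @param cfg A [sim_config()].
#' @return List with `recording` (class `eeg_recording`: `data`
#'   channels x samples, `rate`, `ch_names`) and `ground_truth` (schedule,
#'   delay, gains, modulation windows).
#' @export
synth_eeg <- function(schedule, cfg) {
  stopifnot(inherits(schedule, "percept_schedule"), inherits(cfg, "sim_config"))
  with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    rate <- cfg$eeg_rate
    n <- as.integer(round(schedule$session_length * rate))
    times <- (seq_len(n) - 1L) / rate
    lag <- as.integer(round(cfg$coupling_delay * rate / 1000))
    per_roi <- cfg$eeg_channels %/% 4L
    ch <- roi_channel_names(per_roi)
    defs <- roi_definitions(per_roi)

    A <- stats::rnorm(n + lag) # white latent, unit SD
    A_now <- A[(lag + 1L):(lag + n)]
    A_lag <- A[1:n]
    g <- gated_series(times, schedule, cfg, cfg$coupling_gain_base,
                      cfg$coupling_gain_int, cfg$coupling_gain_dif)
    amp <- gated_series(times, schedule, cfg, 0,
                        cfg$lowfreq_amp_int, cfg$lowfreq_amp_dif)
    osc <- amp * sin(2 * pi * cfg$lowfreq_hz * times)

    bg <- t(pink_noise(n, cfg$eeg_channels)) * cfg$noise_sd
    data <- bg
    rownames(data) <- ch
    fr <- match(defs$front, ch)
    bk <- match(defs$back, ch)
    data[fr, ] <- sweep(data[fr, , drop = FALSE], 2L, A_now + osc, "+")
    data[bk, ] <- sweep(data[bk, , drop = FALSE], 2L, g * A_lag, "+")

    w <- cfg$premod_window / 1000
    windows <- if (length(schedule$switch_times)) {
      data.frame(onset = schedule$switch_times - w,
                 offset = schedule$switch_times,
                 condition = paste0("to_", schedule$percepts[-1L]))
    } else {
      data.frame(onset = numeric(0), offset = numeric(0),
                 condition = character(0))
    }

    list(recording = structure(list(data = data, rate = rate, ch_names = ch,
                                    start_time = 0),
                               class = "eeg_recording"),
         ground_truth = list(schedule = schedule,
                             coupling_delay = cfg$coupling_delay,
                             gains = c(base = cfg$coupling_gain_base,
                                       to_INT = cfg$coupling_gain_int,
                                       to_DIF = cfg$coupling_gain_dif),
                             lowfreq = c(hz = cfg$lowfreq_hz,
                                         to_INT = cfg$lowfreq_amp_int,
                                         to_DIF = cfg$lowfreq_amp_dif),
                             windows = windows))
  })
}

#' Directly synthesize ROI-averaged switch-locked epochs
#'
#' Generates front- and back-ROI epochs time-locked to a perceptual switch
#' at `t = 0` of the given `condition`, with the same coupling and
#' oscillation structure as [synth_eeg()] (modulations active in
#' `[-premod_window, 0]` ms).  Much cheaper than cutting epochs out of full
#' sessions; used for estimator validation and calibration studies.
#'
#' @param n_epochs Number of epochs.
#' @param condition `"to_INT"` or `"to_DIF"` (selects the gated gain and
#'   oscillation amplitude).
#' @param cfg A [sim_config()]; `cfg$seed` seeds the draw when not `NULL`.
#' @param window Epoch window in ms relative to the switch.
#' @return List with `front` and `back` [roi_epochs()] and a `ground_truth`
#'   list.
#' @export
synth_epochs <- function(n_epochs, condition = c("to_INT", "to_DIF"),
                         cfg = sim_config(), window = c(-1000, 100)) {
  condition <- match.arg(condition)
  stopifnot(n_epochs >= 1, window[1] < window[2])
  with_seed(cfg$seed, {
    rate <- cfg$eeg_rate
    step <- 1000 / rate
    times <- seq(window[1], window[2], by = step)
    nT <- length(times)
    lag <- as.integer(round(cfg$coupling_delay * rate / 1000))

    gain <- if (condition == "to_INT") cfg$coupling_gain_int else cfg$coupling_gain_dif
    amp <- if (condition == "to_INT") cfg$lowfreq_amp_int else cfg$lowfreq_amp_dif
    active <- times >= -cfg$premod_window & times <= 0
    g <- ifelse(active, gain, cfg$coupling_gain_base)

    A <- matrix(stats::rnorm(n_epochs * (nT + lag)), n_epochs, nT + lag)
    A_now <- A[, (lag + 1L):(lag + nT), drop = FALSE]
    A_lag <- A[, 1:nT, drop = FALSE]
    bgF <- t(pink_noise(nT, n_epochs)) * cfg$noise_sd
    bgB <- t(pink_noise(nT, n_epochs)) * cfg$noise_sd
    phase <- stats::runif(n_epochs, 0, 2 * pi)
    osc <- (amp * outer(rep(1, n_epochs), as.numeric(active))) *
      sin(outer(phase, 2 * pi * cfg$lowfreq_hz * times / 1000, "+"))

    front <- bgF + A_now + osc
    back <- bgB + sweep(A_lag, 2L, g, "*")
    list(front = roi_epochs(front, times = times, rate = rate,
                            roi = "front", condition = condition),
         back = roi_epochs(back, times = times, rate = rate,
                           roi = "back", condition = condition),
         ground_truth = list(condition = condition,
                             coupling_delay = cfg$coupling_delay,
                             gain = gain, lowfreq_amp = amp,
                             active_window = c(-cfg$premod_window, 0)))
  })
}

#' Synthesize labelled slow-phase-velocity epochs for the decoder
#'
#' Each epoch contains a slope reversal at its centre (with uniform jitter):
#' position traces are generated with the session machinery of
#' [synth_okn()] (sigmoidal slope reversal, optional fast-phase resets,
#' additive noise), then reduced to slow-phase velocity with
#' [slow_phase_velocity()].  Labels name the post-switch percept.
#'
#' @param n_per_class Epochs per class.
#' @param cfg A [sim_config()]; `okn_slow_speed`, `transition_width`,
#'   `fast_phase_rate` and `noise_sd` shape the task difficulty.
#' @param input_length Samples per epoch (default 625 at 500 Hz = 1.25 s,
#'   centred on the switch).
#' @param jitter_ms Uniform jitter of the switch position (ms).
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `x` (epochs x samples velocity matrix), `y` (factor
#'   `"to_INT"`/`"to_DIF"`) and `rate`.
#' @export
synth_okn_epochs <- function(n_per_class = 100, cfg = sim_config(),
                             input_length = 625, jitter_ms = 100,
                             seed = cfg$seed) {
  stopifnot(n_per_class >= 1, input_length >= 50)
  with_seed(seed, {
    rate <- cfg$okn_rate
    dt <- 1 / rate
    pad <- as.integer(ceiling(0.3 * rate)) # margin for the velocity kernels
    nT <- input_length + 2L * pad
    t_rel <- (seq_len(nT) - 1L - (nT - 1L) / 2) * dt
    n <- 2L * n_per_class
    labels <- rep(c("to_INT", "to_DIF"), each = n_per_class)
    x <- matrix(0, n, input_length)
    tau <- cfg$transition_width / 8
    for (i in seq_len(n)) {
      t0 <- stats::runif(1, -jitter_ms, jitter_ms) / 1000
      sgn <- if (labels[i] == "to_INT") -1 else 1 # post-switch slope sign
      slope <- cfg$okn_slow_speed * sgn * (2 * stats::plogis((t_rel - t0) / tau) - 1)
      pos <- cumsum(slope) * dt
      if (cfg$fast_phase_rate > 0) {
        n_sac <- stats::rpois(1L, cfg$fast_phase_rate * nT * dt)
        if (n_sac > 0L) {
          idx <- sort(sample.int(nT, min(n_sac, nT)))
          for (j in idx) pos[j:nT] <- pos[j:nT] - pos[j]
        }
      }
      if (cfg$noise_sd > 0) pos <- pos + stats::rnorm(nT, sd = cfg$noise_sd * 0.02)
      tr <- oculomotor_trace(pos, rate = rate)
      v <- slow_phase_velocity(tr)$values
      x[i, ] <- v[(pad + 1L):(pad + input_length)]
    }
    ord <- sample.int(n)
    list(x = x[ord, , drop = FALSE],
         y = factor(labels[ord], levels = c("to_INT", "to_DIF")),
         rate = rate)
  })
}

#' Generate a complete synthetic session
#'
#' Draws a percept schedule from the configured gamma distribution, then the
#' OKN trace, the EEG recording and the event table (ground-truth switches
#' plus simulated button presses lagging each switch by a
#' direction-specific Gaussian report delay).
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_session`: list with `schedule`, `okn`, `eeg`,
#'   `events` (data frame `time`, `type`, `label`), `ground_truth`, `config`.
#' @export
synth_session <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_draw <- as.integer(ceiling(cfg$session_length /
                                 (cfg$gamma_shape * cfg$gamma_scale) * 3) + 10)
  durations <- sample_dominance_durations(cfg$gamma_shape, cfg$gamma_scale,
                                          n_draw, seed = cfg$seed)
  schedule <- build_schedule(durations, cfg$session_length, cfg$initial_percept)
  okn <- synth_okn(schedule, cfg)
  eeg <- synth_eeg(schedule, cfg)
  sw <- switch_directions(schedule)
  press <- with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 2L, {
    if (nrow(sw)) {
      mu <- ifelse(sw$direction == "to_INT", cfg$report_delay_mean_int,
                   cfg$report_delay_mean_dif)
      sw$time + stats::rnorm(nrow(sw), mu, cfg$report_delay_sd)
    } else numeric(0)
  })
  events <- rbind(
    data.frame(time = sw$time, type = "switch", label = sw$direction),
    data.frame(time = press[press < cfg$session_length], type = "button",
               label = sw$direction[press < cfg$session_length]))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(schedule = schedule, okn = okn, eeg = eeg$recording,
                 events = events, ground_truth = eeg$ground_truth,
                 config = cfg),
            class = "synthetic_session")
}

#' Write / read a session container
#'
#' The container stores all arrays and metadata of a session in a single
#' file; round-trips are bit-exact.  Events can additionally be exported as
#' tab-separated text with [export_events()].
#'
#' @param session A `synthetic_session` (or any R list).
#' @param path File path.
#' @return `write_session` returns `path` invisibly; `read_session` the
#'   restored object.
#' @export
write_session <- function(session, path) {
  saveRDS(session, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) readRDS(path)

#' Export an event table as tab-separated text
#'
#' Columns `time_s`, `type`, `label`.
#'
#' @param events Data frame with `time`, `type`, `label`.
#' @param path Output path.
#' @export
export_events <- function(events, path) {
  out <- data.frame(time_s = events$time, type = events$type,
                    label = events$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.percept_schedule <- function(x, ...) {
  cat(sprintf("<percept_schedule> %d switches over %.1f s (first percept %s)\n",
              length(x$switch_times), x$session_length, x$percepts[1L]))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> gamma(%.2g, %.2g s), session %.0f s, ",
                     "EEG %d ch @ %g Hz, delay %g ms, gains %g/%g/%g\n"),
              x$gamma_shape, x$gamma_scale, x$session_length, x$eeg_channels,
              x$eeg_rate, x$coupling_delay, x$coupling_gain_base,
              x$coupling_gain_int, x$coupling_gain_dif))
  invisible(x)
}
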