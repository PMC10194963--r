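# OKN preprocessing, slow-phase velocity, switch detection, gamma fits and
# report-delay summaries.

test_that("blink interpolation restores a linear signal exactly", {
  tr <- make_ramp_trace(1000, 500, 1)
  gap <- 400:500
  broken <- tr
  broken$samples[gap] <- NA
  broken$blink_events <- data.frame(onset = 399 / 500, offset = 500 / 500)
  fixed <- interpolate_blinks(broken, pad = 0)
  expect_equal(fixed$samples, tr$samples, tolerance = 1e-10)
  expect_false(anyNA(fixed$samples))
  # no blinks -> identity
  expect_identical(interpolate_blinks(tr)$samples, tr$samples)
})

test_that("blink padding rewrites the expected number of samples", {
  rate <- 500
  n <- 3000
  tr <- oculomotor_trace(sin(seq_len(n) / 50), rate = rate)
  onset <- 2.0
  offset <- 2.2 # 200 ms blink
  tr$blink_events <- data.frame(onset = onset, offset = offset)
  out <- interpolate_blinks(tr, pad = 150)
  changed <- which(out$samples != tr$samples)
  # [onset - 150 ms, offset + 150 ms] inclusive at 500 Hz: 0.5 s -> 251 samples
  expect_lte(abs(length(changed) - 251), 2)
})

test_that("boundary blinks hold the nearest valid value with a warning", {
  tr <- make_ramp_trace(500, 500, 1)
  tr$samples[1:20] <- NA
  tr$blink_events <- data.frame(onset = 0, offset = 19 / 500)
  expect_warning(out <- interpolate_blinks(tr, pad = 0), "boundary")
  expect_false(anyNA(out$samples))
})

test_that("butterworth low-pass matches its analytic magnitude response", {
  rate <- 500
  t <- seq(0, 4, by = 1 / rate)
  # squared (forward-backward) magnitude of a 3rd-order butterworth
  gain2 <- function(f, fc) 1 / (1 + (f / fc)^(2 * 3))
  for (f0 in c(1, 50)) {
    tr <- oculomotor_trace(sin(2 * pi * f0 * t), rate = rate)
    out <- lowpass_filter(tr, cutoff = 10, order = 3)
    mid <- out$samples[500:1500]
    amp <- (max(mid) - min(mid)) / 2
    expect_lt(abs(amp - gain2(f0, 10)), 0.01)
  }
  # DC passes unchanged (gain 1 at 0 Hz)
  dc <- oculomotor_trace(rep(2, 1000), rate = rate)
  expect_equal(lowpass_filter(dc)$samples, rep(2, 1000), tolerance = 1e-7)
  expect_error(lowpass_filter(make_ramp_trace(), cutoff = 300), "Nyquist")
})

test_that("deconvolution recovers a known event kernel, even with overlap", {
  set.seed(31)
  rate <- 100
  n <- 12000
  kern <- 0.8 * exp(-(0:99) / 20) * sin((0:99) / 8)
  for (gap in c(3.0, 0.6)) { # well separated, then strongly overlapping
    # jittered onsets keep the shifted-indicator design well conditioned
    onsets <- cumsum(runif(floor(110 / gap), 0.7 * gap, 1.3 * gap)) + 2
    onsets <- onsets[onsets < n / rate - 2]
    x <- rnorm(n, sd = 0.2)
    for (o in onsets) {
      i0 <- round(o * rate) + 1
      x[i0:(i0 + 99)] <- x[i0:(i0 + 99)] + kern
    }
    tr <- oculomotor_trace(x, rate = rate,
                           blink_events = data.frame(onset = onsets,
                                                     offset = onsets + 0.1))
    out <- remove_event_responses(tr, window = c(0, 0.99))
    est <- attr(out, "kernels")$blink$response
    expect_gt(cor(est, kern), 0.95)
    expect_lt(var(out$samples), 1.3 * 0.2^2)
  }
  # no events -> identity
  tr0 <- make_ramp_trace(500, 100)
  expect_identical(remove_event_responses(tr0)$samples, tr0$samples)
})

test_that("percent signal change behaves per definition", {
  tr <- oculomotor_trace(rep(5, 100), rate = 100)
  expect_equal(to_percent_signal_change(tr)$samples, rep(0, 100))
  tr2 <- oculomotor_trace(c(rep(1, 99), 1.1), rate = 100)
  expect_equal(to_percent_signal_change(tr2, block_mean = 1)$samples[100], 10)
  tr3 <- oculomotor_trace(rnorm(1000), rate = 100)
  psc <- to_percent_signal_change(tr3)
  expect_lt(abs(mean(psc$samples)), 1e-9)
  expect_error(to_percent_signal_change(tr3, block_mean = 0), "zero")
})

test_that("slow-phase velocity of a ramp equals slope per sample step", {
  a <- 2.5
  tr <- make_ramp_trace(3000, 500, a)
  v <- slow_phase_velocity(tr)
  interior <- v$values[500:2500]
  expect_equal(interior, rep(a * 0.002, length(interior)), tolerance = 1e-6)
  # linearity: sign-flipped trace gives sign-flipped velocity
  trn <- tr
  trn$samples <- -trn$samples
  expect_equal(slow_phase_velocity(trn)$values, -v$values, tolerance = 1e-12)
  expect_error(slow_phase_velocity(make_ramp_trace(50, 500)), "shorter")
})

test_that("velocity zero-crossings sit at the extrema of a sinusoid", {
  rate <- 500
  t <- seq(0, 10, by = 1 / rate)
  tr <- oculomotor_trace(sin(2 * pi * t / 2), rate = rate)
  v <- slow_phase_velocity(tr)
  det <- detect_switches(v, min_separation = 0.2)
  # extrema of sin(pi t) at t = 0.5, 1.5, ..., 9.5
  expected <- seq(0.5, 9.5, by = 1)
  found <- sapply(expected, function(e) min(abs(det$time - e)))
  expect_true(all(found <= 2 / rate + 1e-9))
})

test_that("switch detection recovers sine crossings with alternation", {
  rate <- 250
  t <- seq(0, 10, by = 1 / rate)
  vel <- structure(list(values = sin(2 * pi * t / 2), rate = rate,
                        start_time = 0,
                        provenance = list(), unreliable_ms = 0),
                   class = "slow_phase_velocity")
  det <- detect_switches(vel, min_separation = 0.2, hysteresis = 0)
  expect_equal(det$time, 1:9, tolerance = 1e-3)
  expect_true(all(det$direction[-1] != det$direction[-nrow(det)]))
  # chatter below the hysteresis produces no events
  vel$values <- 0.01 * sin(2 * pi * t * 5)
  expect_equal(nrow(detect_switches(vel, hysteresis = 0.5)), 0)
  vel$values <- rep(0, length(t))
  expect_warning(out <- detect_switches(vel), "all-zero")
  expect_equal(nrow(out), 0)
})

test_that("full OKN pipeline recovers scheduled switches on clean sessions", {
  # clean = no blinks or fast phases; sensor noise retained
  hits <- 0
  total <- 0
  n_det <- 0
  for (seed in 1:3) {
    cfg <- sim_config(fast_phase_rate = 0, blink_rate = 0, seed = seed)
    ses <- synth_session(cfg)
    v <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
    det <- detect_switches(v)
    truth <- switch_directions(ses$schedule)
    err <- sapply(truth$time, function(tt) min(abs(det$time - tt)))
    hits <- hits + sum(err <= 0.1)
    total <- total + nrow(truth)
    n_det <- n_det + nrow(det)
    expect_true(all(det$direction[-1] != det$direction[-nrow(det)]))
  }
  expect_gte(hits / total, 0.95)       # recall
  expect_gte(hits / n_det, 0.95)       # precision (spurious crossings rare)
})

test_that("blink-laden sessions still recover most switches", {
  # blinks overlapping a transition displace its interpolated crossing, so
  # tolerances here are wider than on clean traces
  err <- unlist(lapply(4:5, function(seed) {
    cfg <- sim_config(fast_phase_rate = 0, seed = seed) # default blink rate
    ses <- synth_session(cfg)
    v <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
    det <- detect_switches(v)
    truth <- switch_directions(ses$schedule)
    sapply(truth$time, function(tt) min(abs(det$time - tt)))
  }))
  expect_gte(mean(err <= 0.1), 0.8)
  expect_gte(mean(err <= 0.25), 0.95)
})

test_that("interpolate+filter is near-idempotent on a clean trace", {
  cfg <- sim_config(blink_rate = 0, fast_phase_rate = 0, noise_sd = 0,
                    seed = 2, session_length = 30)
  ses <- synth_session(cfg)
  clean <- lowpass_filter(interpolate_blinks(ses$okn))
  again <- lowpass_filter(interpolate_blinks(clean))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(again$samples) - rms(clean$samples)) / rms(clean$samples),
            0.01)
})

test_that("detection degrades monotonically with trace noise", {
  recall_at <- function(noise) {
    cfg <- sim_config(fast_phase_rate = 0, blink_rate = 0, noise_sd = noise,
                      seed = 5)
    ses <- synth_session(cfg)
    v <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
    det <- detect_switches(v)
    truth <- switch_directions(ses$schedule)
    if (!nrow(det)) return(0)
    mean(sapply(truth$time, function(tt) min(abs(det$time - tt))) <= 0.1)
  }
  r <- vapply(c(0.5, 20, 80), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0.05)) # non-increasing up to sampling noise
  expect_gt(r[1], r[3])
})

test_that("gamma fitting recovers parameters and flags degeneracy", {
  d <- sample_dominance_durations(3, 1.5, 2000, seed = 8)
  fit <- fit_gamma(d)
  expect_lt(abs(fit$shape - 3) / 3, 0.1)
  expect_lt(abs(fit$scale - 1.5) / 1.5, 0.1)

  e <- sample_dominance_durations(1, 2, 2000, seed = 9)
  expect_lt(abs(fit_gamma(e)$shape - 1), 0.1)

  expect_error(fit_gamma(rep(2, 100)), "degenerate|failed")
  expect_error(fit_gamma(c(-1, rexp(30))), "positive")
  expect_error(fit_gamma(rexp(10)), "at least 20")
})

test_that("report delays pair presses to preceding crossings", {
  okn <- data.frame(time = c(1, 5), direction = c("to_INT", "to_DIF"))
  bp <- data.frame(time = c(1.4, 5.6), direction = c("to_INT", "to_DIF"))
  res <- okn_report_delay(okn, bp, max_pairing = 1)
  expect_equal(res$delays$delay, c(0.4, 0.6))
  expect_equal(res$n_unpaired, 0)
  # press with no crossing in range is dropped and counted
  bp2 <- rbind(bp, data.frame(time = 9, direction = "to_INT"))
  res2 <- okn_report_delay(okn, bp2, max_pairing = 1)
  expect_equal(res2$n_unpaired, 1)
  expect_error(okn_report_delay(okn[0, ], bp), "non-empty")
})

test_that("the delay contrast has power against a 100 ms shift", {
  # 40 subjects x 50 switches, INT delays N(0.5, 0.1) vs DIF N(0.4, 0.1)
  detect_rate <- mean(vapply(1:100, function(rep) {
    set.seed(4000 + rep)
    rows <- lapply(1:40, function(s) {
      times <- cumsum(runif(50, 3, 6))
      dirs <- rep(c("to_INT", "to_DIF"), 25)
      mu <- ifelse(dirs == "to_INT", 0.5, 0.4)
      list(okn = data.frame(subject = s, time = times, direction = dirs),
           bp = data.frame(subject = s, time = times + rnorm(50, mu, 0.1),
                           direction = dirs))
    })
    okn <- do.call(rbind, lapply(rows, `[[`, "okn"))
    bp <- do.call(rbind, lapply(rows, `[[`, "bp"))
    res <- okn_report_delay(okn, bp, max_pairing = 1.5)
    est <- unname(res$t_test$estimate)
    res$t_test$p.value < 0.05 && est > 0
  }, logical(1)))
  expect_gt(detect_rate, 0.9)
})
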