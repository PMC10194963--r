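# EEG preprocessing, rejection rules, event filtering, ROI averaging and
# delimited-text I/O.

make_recording <- function(n_ch = 8, n_s = 2000, rate = 500, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n_s), n_ch, n_s), rate = rate)
}

test_that("preprocessing removes DC, notches line noise and re-references", {
  rate <- 500
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  base <- rbind(matrix(rnorm(6 * length(t)), 6),
                10 + 0 * t,                 # pure DC offset
                sin(2 * pi * 50 * t))       # pure line noise
  rec <- eeg_recording(base, rate = rate)
  out <- preprocess_eeg(rec, target_rate = 250)
  expect_equal(out$rate, 250)
  expect_equal(ncol(out$data), 1000)
  # average reference: zero mean across channels at every sample
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
})

test_that("the band-pass edge suppresses DC and the notch kills 50 Hz", {
  rate <- 250
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  x <- rbind(10 + 0 * t, sin(2 * pi * 50 * t), 0 * t, 0 * t)
  rec <- eeg_recording(x, rate = rate)
  out <- preprocess_eeg(rec, target_rate = 250)
  mid <- 500:1500
  # before average reference the DC row would keep <1% of its offset;
  # check via the row-space: DC row minus its pre-reference twin
  no_ref <- {
    bp <- signal::butter(4, c(1, 100) / 125, "pass")
    as.numeric(signal::filtfilt(bp, 10 + 0 * t))
  }
  expect_lt(max(abs(no_ref[mid])), 0.1)
  notch_row <- {
    bp <- signal::butter(4, c(1, 100) / 125, "pass")
    ns <- signal::butter(2, c(48, 52) / 125, "stop")
    as.numeric(signal::filtfilt(ns, signal::filtfilt(bp, sin(2 * pi * 50 * t))))
  }
  # > 20 dB attenuation
  expect_lt(max(abs(notch_row[mid])), 0.1)
})

test_that("variance-outlier channels are flagged symmetrically", {
  rec <- make_recording(10, 4000)
  res <- reject_channels(rec)
  expect_length(res$drop, 0)
  rec$data[3, ] <- rec$data[3, ] * 10
  res2 <- reject_channels(rec)
  expect_equal(res2$drop, rec$ch_names[3])
  # flags invariant to channel ordering
  perm <- c(5:10, 1:4)
  rec3 <- eeg_recording(rec$data[perm, ], rate = rec$rate,
                        ch_names = rec$ch_names[perm])
  expect_setequal(reject_channels(rec3)$drop, res2$drop)
  expect_error(reject_channels(make_recording(4)), "8 channels")
})

test_that("switch-event filtering applies interval/repetition/window rules", {
  ev <- data.frame(time = c(0, 1.5, 5, 9),
                   direction = c("to_INT", "to_DIF", "to_INT", "to_DIF"))
  res <- filter_switch_events(ev, min_interval = 2, window = c(-500, 500))
  expect_equal(res$events$time, c(0, 5, 9))
  expect_equal(unname(res$log["interval"]), 1)

  ev2 <- data.frame(time = c(0, 5, 10),
                    direction = c("to_INT", "to_INT", "to_DIF"))
  res2 <- filter_switch_events(ev2, window = c(-500, 500))
  expect_equal(res2$events$time, c(0, 10))
  expect_equal(unname(res2$log["repetition"]), 1)

  # an event whose epoch window contains a later response is removed
  ev3 <- data.frame(time = c(0, 5, 5.3),
                    direction = c("to_INT", "to_DIF", "to_INT"))
  res3 <- filter_switch_events(ev3, min_interval = 2, window = c(-2000, 500))
  expect_equal(res3$events$time, 0)
  expect_equal(unname(res3$log["multi_response"]), 1) # event at 5
  expect_equal(unname(res3$log["interval"]), 1)       # event at 5.3
  expect_error(filter_switch_events(ev[c(2, 1), ]), "sorted")
})

test_that("retained events have quiet pre-switch histories on real schedules", {
  cfg <- sim_config(seed = 30)
  ses <- synth_session(cfg)
  sw <- ses$events[ses$events$type == "switch", ]
  ev <- data.frame(time = sw$time, direction = sw$label)
  res <- filter_switch_events(ev, min_interval = 2, window = c(-2000, 500))
  kept <- res$events
  for (i in seq_len(nrow(kept))) {
    prior <- ev$time[ev$time < kept$time[i]]
    if (length(prior)) expect_gte(kept$time[i] - max(prior), 2)
  }
  expect_equal(unname(res$log["total"]),
               unname(res$log["retained"] + res$log["interval"] +
                        res$log["repetition"] + res$log["multi_response"]))
})

test_that("epoching rejects by amplitude and slope and conserves counts", {
  rate <- 250
  n_s <- 5000
  data <- matrix(0, 4, n_s)
  rec <- eeg_recording(data, rate = rate)
  ev <- data.frame(time = c(3, 6, 9, 12, 0.5),
                   direction = rep("to_INT", 5))
  # epoch 2: a single 200 uV spike;  epoch 3: 80 uV linear drift;
  # epoch 4: 40 uV drift (retained); epoch 5: too close to the edge
  win <- c(-2000, 500)
  rel <- seq(round(win[1] / 1000 * rate), round(win[2] / 1000 * rate))
  rec$data[2, round(6 * rate) + 1] <- 200
  rec$data[3, round(9 * rate) + 1 + rel] <- seq(-40, 40, length.out = length(rel))
  rec$data[4, round(12 * rate) + 1 + rel] <- seq(-20, 20, length.out = length(rel))
  res <- epoch_and_reject(rec, ev, window = win)
  expect_equal(unname(res$log),
               unname(c(total = 5, retained = 2, edge = 1, amplitude = 1,
                        slope = 1)))
  expect_equal(dim(res$data)[1], 2)
  expect_equal(dim(res$data)[3], length(rel))
  # all-zero recording: nothing rejected except the edge case
  rec0 <- eeg_recording(matrix(0, 4, n_s), rate = rate)
  res0 <- epoch_and_reject(rec0, ev, window = win)
  expect_equal(unname(res0$log[["retained"]]), 4)
})

test_that("ROI averaging reduces channels as expected", {
  rate <- 250
  defs <- roi_definitions()
  expect_length(defs$front, 6)
  expect_length(defs$back, 6)
  expect_equal(length(intersect(defs$front, defs$back)), 0)

  n_t <- 626
  ev <- data.frame(time = 4, direction = "to_INT")
  sig <- sin(seq_len(2000) / 40)
  data <- matrix(rep(sig, each = 24), 24, 2000)
  rec <- eeg_recording(data, rate = rate,
                       ch_names = unlist(roi_definitions(), use.names = FALSE))
  eps <- epoch_and_reject(rec, ev, window = c(-2000, 500),
                          amp_bound = 1e6, slope_bound = 1e6)
  avg <- roi_average(eps, "front")
  expect_equal(dim(avg$values), c(1, n_t))
  expect_equal(as.numeric(avg$values[1, ]), eps$data[1, 1, ])
  # opposite-polarity pair cancels
  rec$data["Fp1", ] <- sig
  rec$data["Fp2", ] <- -sig
  eps2 <- epoch_and_reject(rec, ev, window = c(-2000, 500),
                           amp_bound = 1e6, slope_bound = 1e6)
  avg2 <- roi_average(eps2, c("Fp1", "Fp2"))
  expect_lt(max(abs(avg2$values)), 1e-12)
  expect_error(roi_average(eps2, c("Fp1", "Zz9")), "Zz9")
})

test_that("eye-tracker and switch-event text files round-trip", {
  dir <- withr::local_tempdir()
  t <- seq(0, 2, by = 1 / 500)
  samp <- data.frame(time = t, x = sin(t))
  sp <- file.path(dir, "samples.tsv")
  utils::write.table(samp, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- read_eye_samples(sp)
  expect_equal(tr$rate, 500)
  expect_equal(tr$samples, samp$x)

  evp <- file.path(dir, "events.tsv")
  evd <- data.frame(onset = c(0.5, 1.2), offset = c(0.7, 1.3),
                    type = c("blink", "saccade"))
  utils::write.table(evd, evp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_eye_events(evp)$type, evd$type)

  sw <- data.frame(time = c(1, 2.5), direction = c("to_INT", "to_DIF"),
                   source = "okn_crossing")
  swp <- file.path(dir, "switches.tsv")
  write_switch_events(sw, swp)
  back <- read_switch_events(swp)
  expect_equal(back$time, sw$time)
  expect_equal(back$direction, sw$direction)
})
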