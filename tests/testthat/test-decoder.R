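# Convolutional decoder: splits, architecture arithmetic, training,
# evaluation and cross-classification.

test_that("stratified splits are exact, disjoint and reproducible", {
  labels <- rep(c("to_INT", "to_DIF"), each = 500)
  sp <- split_spec(seed = 3)
  idx <- stratified_split(labels, sp)
  expect_equal(lengths(idx), c(train = 700L, val = 150L, test = 150L))
  for (part in idx) {
    expect_equal(unname(table(labels[part])), unname(table(labels[part])))
    expect_equal(as.vector(table(labels[part])),
                 rep(length(part) / 2, 2))
  }
  # partition: union is everything, pairwise intersections empty
  expect_setequal(unlist(idx), seq_along(labels))
  expect_length(intersect(idx$train, idx$val), 0)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_length(intersect(idx$val, idx$test), 0)
  expect_identical(idx, stratified_split(labels, sp))
  expect_error(stratified_split(rep("a", 10)), "2 classes")
  expect_error(stratified_split(c(rep("a", 10), "b", "b")), "3 examples")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("layer shapes follow the stride and pooling arithmetic", {
  dec <- build_decoder(decoder_spec(seed = 1))
  # L_out = floor((L_in - k)/s) + 1 per layer
  expect_equal(dec$shapes$conv1, c(1L, 625L - 25L + 1L, 8L))       # 601
  expect_equal(dec$shapes$pool1[2], (601L - 5L) %/% 2L + 1L)       # 299
  expect_equal(dec$shapes$conv2, c(8L - 2L + 1L, 299L - 50L + 1L, 16L))
  expect_equal(dec$shapes$pool2[2], (250L - 5L) %/% 2L + 1L)       # 123
  expect_equal(dec$shapes$conv3, c(7L - 2L + 1L, 123L - 75L + 1L, 32L))
  expect_equal(dec$shapes$dense, c(1L, 2L))
  # parameter count: conv 8x25, conv 16x(2x50), conv 32x(2x75x16), dense
  expect_equal(dec$n_params,
               (8 * 25 + 8) + (16 * 100 + 16) + (32 * 2400 + 32) +
                 (2 * 6 * 49 * 32 + 2))
  expect_error(build_decoder(decoder_spec(input_length = 100)),
               "receptive field")
})

test_that("forward passes are calibrated probability vectors", {
  dec <- build_decoder(decoder_spec(seed = 2))
  x <- matrix(rnorm(3 * 625), 3)
  p <- predict(dec, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0))
  # all-zero input with zero biases -> exact symmetry
  p0 <- predict(dec, matrix(0, 1, 625), type = "prob")
  expect_equal(as.numeric(p0), c(0.5, 0.5))
})

test_that("training separates clean percept epochs", {
  dat <- make_decoder_data(200, noise_sd = 0.5, seed = 11)
  idx <- stratified_split(dat$y, split_spec(seed = 5))
  dec <- build_decoder(decoder_spec(seed = 7))
  dec <- train_decoder(dec, dat$x[idx$train, ], dat$y[idx$train],
                       dat$x[idx$val, ], dat$y[idx$val],
                       epochs = 2, batch_size = 64)
  ev <- evaluate_decoder(dec, dat$x[idx$test, ], dat$y[idx$test])
  expect_gte(ev$accuracy, 0.95)
  expect_equal(sum(ev$confusion), length(idx$test))
  # training loss decreases on the separable task (moving average)
  sm <- stats::filter(dec$log$loss, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  # a linear baseline (late-minus-early velocity, logistic fit) confirms
  # the task is separable at the same level
  feat <- function(x) rowMeans(x[, 417:625]) - rowMeans(x[, 1:208])
  df_tr <- data.frame(f = feat(dat$x[idx$train, ]),
                      y = dat$y[idx$train] == "to_DIF")
  fit <- suppressWarnings(glm(y ~ f, data = df_tr, family = binomial()))
  pr <- predict(fit, data.frame(f = feat(dat$x[idx$test, ])))
  base_acc <- mean((pr > 0) == (dat$y[idx$test] == "to_DIF"))
  expect_gte(base_acc, 0.95)
})

test_that("training is deterministic under a fixed seed", {
  dat <- make_decoder_data(40, seed = 21)
  run <- function() {
    dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = 9))
    dec <- train_decoder(dec, dat$x, dat$y, epochs = 1, batch_size = 32)
    dec$layers[[length(dec$layers)]]$W
  }
  expect_identical(run(), run())
})

test_that("shuffled labels collapse accuracy to chance", {
  dat <- make_decoder_data(100, noise_sd = 0.5, seed = 31)
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y_sh <- sample(dat$y)
    dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = s))
    dec <- train_decoder(dec, dat$x[1:140, ], y_sh[1:140],
                         epochs = 3, batch_size = 64, seed = s)
    evaluate_decoder(dec, dat$x[141:200, ], y_sh[141:200])$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.45)
  expect_lte(mean(accs), 0.55)
})

test_that("accuracy does not increase with trace noise", {
  acc_at <- function(noise, seed) {
    dat <- make_decoder_data(80, noise_sd = noise, seed = 40 + seed)
    dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = seed))
    dec <- train_decoder(dec, dat$x[1:112, ], dat$y[1:112],
                         epochs = 3, batch_size = 56, seed = seed)
    evaluate_decoder(dec, dat$x[113:160, ], dat$y[113:160])$accuracy
  }
  levels <- c(0.5, 30, 120)
  means <- vapply(levels, function(nv) {
    mean(vapply(1:5, function(s) acc_at(nv, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.05))
  expect_gt(means[1], means[3])
})

test_that("cross-classification degenerates correctly and flips with labels", {
  dat <- make_decoder_data(80, seed = 51)
  dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = 3))
  dec <- train_decoder(dec, dat$x[1:112, ], dat$y[1:112],
                       epochs = 3, batch_size = 56)
  ho_x <- dat$x[113:160, ]
  ho_y <- dat$y[113:160]
  same <- evaluate_decoder(dec, ho_x, ho_y)
  expect_identical(cross_classify(dec, ho_x, ho_y)$accuracy, same$accuracy)
  # adversarial relabelling: accuracy becomes its complement
  flipped <- factor(ifelse(ho_y == "to_INT", "to_DIF", "to_INT"),
                    levels = levels(ho_y))
  expect_equal(cross_classify(dec, ho_x, flipped)$accuracy,
               1 - same$accuracy)
  expect_error(cross_classify(dec, ho_x[, 1:100], ho_y), "mismatch")
})

test_that("decoder-confirmed switch counts track ground truth", {
  # train once on pooled epochs, then count confirmed switches per subject
  pool <- make_decoder_data(120, seed = 61)
  dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = 4))
  dec <- train_decoder(dec, pool$x, pool$y, epochs = 3, batch_size = 64)
  truth_counts <- integer(10)
  confirmed <- integer(10)
  for (s in 1:10) {
    cfg <- sim_config(fast_phase_rate = 0, seed = 70 + s,
                      session_length = 60 + 15 * s)
    ses <- synth_session(cfg)
    v <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
    det <- detect_switches(v)
    truth_counts[s] <- length(ses$schedule$switch_times)
    if (!nrow(det)) next
    eps <- t(vapply(det$time, function(tt) {
      i0 <- round((tt - v$start_time) * v$rate) - 312
      win <- i0:(i0 + 624)
      if (win[1] < 1 || win[625] > length(v$values)) return(rep(NA_real_, 625))
      v$values[win]
    }, numeric(625)))
    ok <- !apply(eps, 1, anyNA)
    eps <- eps[ok, , drop = FALSE] / stats::sd(eps[ok, ])
    pred <- predict(dec, eps)
    confirmed[s] <- sum(pred == det$direction[ok])
  }
  expect_gt(cor(truth_counts, confirmed), 0.9)
})

test_that("empty or malformed training inputs error", {
  dec <- build_decoder(decoder_spec(conv_mode = "1d", seed = 1))
  expect_error(train_decoder(dec, matrix(0, 0, 625), factor(character(0))),
               "empty")
  expect_error(train_decoder(dec, matrix(0, 4, 100), rep("to_INT", 4)),
               "length")
  expect_error(evaluate_decoder(dec, matrix(0, 0, 625), character(0)),
               "empty")
})
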