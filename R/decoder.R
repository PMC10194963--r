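# Convolutional decoder of perceptual state from single slow-phase-velocity
# OKN epochs.  The network is small enough that forward/backward passes are
# implemented directly as im2col gathers plus BLAS matrix products; training
# is plain mini-batch SGD with momentum on the cross-entropy loss.
#
# Architecture (defaults):
#   input 1 x 625 -> conv 8 @ 1x25 (ReLU, stride 1) -> maxpool 1x5 stride 2
#   -> conv 16 @ 2x50 (ReLU) -> maxpool 1x5 stride 2 -> conv 32 @ 2x75
#   (ReLU) -> dense 2, softmax.
# The 2x50 / 2x75 kernels span pairs of feature maps: after the first pool
# the 8 maps are stacked as the height axis of a single-channel image and
# the later convolutions are genuine 2-D convolutions over (map, time).
# `conv_mode = "1d"` instead treats maps as channels with kernels 50 and 75.

#' Decoder hyperparameters
#'
#' @param input_length Epoch length in samples (1.25 s at 500 Hz).
#' @param conv_mode `"2d"` (kernels span feature-map pairs, the default) or
#'   `"1d"` (kernels span all input channels).
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param validate_every Validation cadence in mini-batches.
#' @param seed Seed controlling weight initialization and shuffling.
#' @return A `decoder_spec` list.
#' @export
decoder_spec <- function(input_length = 625, conv_mode = c("2d", "1d"),
                         learning_rate = 0.01, momentum = 0.9,
                         batch_size = 128, epochs = 30, validate_every = 10,
                         seed = NULL) {
  conv_mode <- match.arg(conv_mode)
  stopifnot(input_length >= 1, learning_rate > 0, momentum >= 0,
            momentum < 1, batch_size >= 1, epochs >= 1, validate_every >= 1)
  structure(list(input_length = as.integer(input_length),
                 conv_mode = conv_mode, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validate_every = as.integer(validate_every), seed = seed),
            class = "decoder_spec")
}

#' Data-split fractions
#'
#' @param train,val,test Split fractions; must sum to 1.
#' @param seed Seed for the stratified shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train = 0.70, val = 0.15, test = 0.15, seed = NULL) {
  if (abs(train + val + test - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  stopifnot(train > 0, val >= 0, test >= 0)
  structure(list(train = train, val = val, test = test, seed = seed),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Within each class the (shuffled) indices are allocated to splits by
#' largest-remainder rounding of the target fractions, so class proportions
#' are equal across splits to within rounding and a balanced set of 1000
#' epochs yields exactly 700/150/150 with 350/75/75 per class.
#'
#' @param labels Class labels (>= 2 classes, each with >= 3 examples).
#' @param spec A [split_spec()].
#' @return List of disjoint, exhaustive index vectors `train`, `val`,
#'   `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 3L)) stop("every class needs at least 3 examples", call. = FALSE)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  fr <- c(spec$train, spec$val, spec$test)
  with_seed(spec$seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      target <- fr * n_c
      base <- floor(target)
      rem <- n_c - sum(base)
      if (rem > 0) {
        extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      cuts <- cumsum(base)
      out$train <- c(out$train, idx[seq_len(base[1L])])
      if (base[2L] > 0) out$val <- c(out$val, idx[(cuts[1L] + 1L):cuts[2L]])
      if (base[3L] > 0) out$test <- c(out$test, idx[(cuts[2L] + 1L):cuts[3L]])
    }
  })
  lapply(out, sort)
}

# ---- layer plumbing ---------------------------------------------------

# per-sample flat layout: col = h + (t-1)*H + (c-1)*H*T
conv_indices <- function(H, T, C, kh, kt) {
  oh <- H - kh + 1L
  ot <- T - kt + 1L
  if (oh < 1L || ot < 1L) {
    stop("input shorter than the receptive field", call. = FALSE)
  }
  pos_h <- rep(seq_len(oh), times = ot)
  pos_t <- rep(seq_len(ot), each = oh)
  taps <- expand.grid(dh = seq_len(kh), dt = seq_len(kt), c = seq_len(C))
  K <- nrow(taps)
  patch <- matrix(0L, oh * ot, K)
  for (k in seq_len(K)) {
    patch[, k] <- (pos_h + taps$dh[k] - 1L) +
      (pos_t + taps$dt[k] - 2L) * H +
      (taps$c[k] - 1L) * H * T
  }
  list(patch = patch, out_h = oh, out_t = ot, K = K)
}

pool_indices <- function(H, T, C, width = 5L, stride = 2L) {
  ot <- (T - width) %/% stride + 1L
  if (ot < 1L) stop("input shorter than the pooling window", call. = FALSE)
  cols <- vector("list", width)
  h <- seq_len(H)
  for (w in seq_len(width)) {
    tpos <- (seq_len(ot) - 1L) * stride + w
    grid <- outer(h, (tpos - 1L) * H, "+")            # H x ot
    cols[[w]] <- as.integer(outer(as.vector(grid), (seq_len(C) - 1L) * H * T,
                                  "+"))
  }
  list(cols = cols, out_t = ot)
}

im2col <- function(X, patch) {
  B <- nrow(X)
  O <- nrow(patch)
  K <- ncol(patch)
  M <- matrix(0, B * O, K)
  for (k in seq_len(K)) M[, k] <- as.vector(X[, patch[, k]])
  M
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained decoder
#'
#' Instantiates the layer stack for the configured input length and
#' convolution mode, with Glorot-uniform weights (seeded via
#' `spec$seed`) and zero biases.  Errors if the input is shorter than the
#' stacked receptive fields require.
#'
#' @param spec A [decoder_spec()].
#' @return An `okn_decoder` with fields `layers`, `shapes`, `n_params`.
#' @export
build_decoder <- function(spec = decoder_spec()) {
  stopifnot(inherits(spec, "decoder_spec"))
  L <- spec$input_length
  layers <- list()
  shapes <- list(input = c(1L, L, 1L))
  add_conv <- function(H, T, C, kh, kt, nf) {
    ci <- conv_indices(H, T, C, kh, kt)
    layers[[length(layers) + 1L]] <<-
      list(type = "conv", patch = ci$patch, W = glorot(nf, ci$K),
           b = numeric(nf), n_filters = nf,
           out = c(ci$out_h, ci$out_t, nf))
    c(ci$out_h, ci$out_t, nf)
  }
  add_pool <- function(H, T, C) {
    pi <- pool_indices(H, T, C)
    layers[[length(layers) + 1L]] <<-
      list(type = "pool", cols = pi$cols, in_len = H * T * C,
           out = c(H, pi$out_t, C))
    c(H, pi$out_t, C)
  }
  with_seed(spec$seed, {
    s <- c(1L, L, 1L)
    s <- add_conv(s[1], s[2], s[3], 1L, 25L, 8L)
    shapes$conv1 <- s
    s <- add_pool(s[1], s[2], s[3])
    shapes$pool1 <- s
    if (spec$conv_mode == "2d") {
      # stack the 8 maps as the height axis of a 1-channel image
      H <- s[3]; T <- s[2]
      # out col c + (t-1)*H  <-  in col t + (c-1)*T
      src <- rep(seq_len(T), each = H) + (rep(seq_len(H), times = T) - 1L) * T
      layers[[length(layers) + 1L]] <- list(type = "permute", src = src)
      s <- c(H, T, 1L)
      shapes$stack <- s
      s <- add_conv(s[1], s[2], s[3], 2L, 50L, 16L)
    } else {
      s <- add_conv(s[1], s[2], s[3], 1L, 50L, 16L)
    }
    shapes$conv2 <- s
    s <- add_pool(s[1], s[2], s[3])
    shapes$pool2 <- s
    if (spec$conv_mode == "2d") {
      s <- add_conv(s[1], s[2], s[3], 2L, 75L, 32L)
    } else {
      s <- add_conv(s[1], s[2], s[3], 1L, 75L, 32L)
    }
    shapes$conv3 <- s
    nf <- prod(s)
    layers[[length(layers) + 1L]] <- list(type = "dense", W = glorot(2L, nf),
                                          b = numeric(2L))
    shapes$dense <- c(1L, 2L)
  })
  n_params <- sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  structure(list(spec = spec, layers = layers, shapes = shapes,
                 n_params = n_params,
                 classes = c("to_INT", "to_DIF")),
            class = "okn_decoder")
}

net_forward <- function(net, X, keep_cache = FALSE) {
  B <- nrow(X)
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      M <- im2col(X, l$patch)
      Z <- M %*% t(l$W)
      Z <- sweep(Z, 2L, l$b, "+")
      A <- Z * (Z > 0)
      if (keep_cache) caches[[li]] <- list(M = M, mask = Z > 0, B = B)
      dim(A) <- c(B, nrow(l$patch) * l$n_filters)
      X <- A
    } else if (l$type == "pool") {
      best <- X[, l$cols[[1L]], drop = FALSE]
      arg <- matrix(1L, nrow(best), ncol(best))
      for (w in 2L:length(l$cols)) {
        cand <- X[, l$cols[[w]], drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- w
      }
      if (keep_cache) caches[[li]] <- list(arg = arg, in_len = l$in_len)
      X <- best
    } else if (l$type == "permute") {
      if (keep_cache) caches[[li]] <- list(src = l$src)
      X <- X[, l$src, drop = FALSE]
    } else { # dense
      logits <- X %*% t(l$W)
      logits <- sweep(logits, 2L, l$b, "+")
      if (keep_cache) caches[[li]] <- list(A = X)
      X <- logits
    }
  }
  mx <- apply(X, 1L, max)
  e <- exp(X - mx)
  probs <- e / rowSums(e)
  list(probs = probs, caches = caches)
}

net_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  d <- dlogits
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cc <- caches[[li]]
    if (l$type == "dense") {
      grads[[li]] <- list(W = t(d) %*% cc$A, b = colSums(d))
      d <- d %*% l$W
    } else if (l$type == "permute") {
      dd <- matrix(0, nrow(d), length(cc$src))
      dd[, cc$src] <- d
      d <- dd
    } else if (l$type == "pool") {
      B <- nrow(d)
      dX <- matrix(0, B, cc$in_len)
      for (w in seq_along(l$cols)) {
        sel <- cc$arg == w
        if (any(sel)) {
          dX[, l$cols[[w]]] <- dX[, l$cols[[w]]] + d * sel
        }
      }
      d <- dX
    } else { # conv
      B <- cc$B
      O <- nrow(l$patch)
      dZ <- d
      dim(dZ) <- c(B * O, l$n_filters)
      dZ <- dZ * cc$mask
      grads[[li]] <- list(W = t(dZ) %*% cc$M, b = colSums(dZ))
      if (li > 1L) {
        dM <- dZ %*% l$W
        in_len <- max(l$patch)
        dX <- matrix(0, B, in_len)
        for (k in seq_len(ncol(l$patch))) {
          cols <- l$patch[, k]
          dX[, cols] <- dX[, cols] + matrix(dM[, k], B, O)
        }
        d <- dX
      }
    }
  }
  grads
}

net_predict_probs <- function(net, X, chunk = 256L) {
  n <- nrow(X)
  out <- matrix(0, n, 2L)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[i:j, ] <- net_forward(net, X[i:j, , drop = FALSE])$probs
    i <- j + 1L
  }
  out
}

label_matrix <- function(y, classes) {
  y <- factor(y, levels = classes)
  if (anyNA(y)) stop("labels outside the decoder's classes", call. = FALSE)
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Train the decoder
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss.  The training set is reshuffled at the start of
#' every epoch; validation accuracy is evaluated every
#' `spec$validate_every` mini-batches when a validation set is supplied.
#' Initialization and shuffling are fully determined by the seeds, so
#' training is reproducible.
#'
#' @param decoder An untrained [build_decoder()] network.
#' @param x_train,y_train Training epochs (rows) and labels.
#' @param x_val,y_val Optional validation set.
#' @param epochs,batch_size,learning_rate Overrides of the spec values.
#' @param seed Seed for epoch shuffling (defaults to `spec$seed`).
#' @return The trained decoder; the training log (one row per mini-batch:
#'   `epoch`, `batch`, `loss`, `val_accuracy`) is stored as `$log`.
#' @export
train_decoder <- function(decoder, x_train, y_train, x_val = NULL,
                          y_val = NULL, epochs = NULL, batch_size = NULL,
                          learning_rate = NULL, seed = NULL) {
  stopifnot(inherits(decoder, "okn_decoder"))
  x_train <- as.matrix(x_train)
  if (!nrow(x_train)) stop("empty training set", call. = FALSE)
  if (ncol(x_train) != decoder$spec$input_length) {
    stop("epoch length does not match the decoder input", call. = FALSE)
  }
  spec <- decoder$spec
  n_ep <- epochs %||% spec$epochs
  bs <- batch_size %||% spec$batch_size
  lr <- learning_rate %||% spec$learning_rate
  seed <- seed %||% (if (is.null(spec$seed)) NULL else spec$seed + 1L)
  Y <- label_matrix(y_train, decoder$classes)
  n <- nrow(x_train)

  vel <- lapply(decoder$layers, function(l) {
    if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0)
  })
  log_rows <- list()
  batch_no <- 0L
  with_seed(seed, {
    for (ep in seq_len(n_ep)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(n, start + bs - 1L)]
        B <- length(idx)
        fw <- net_forward(decoder, x_train[idx, , drop = FALSE],
                          keep_cache = TRUE)
        p <- pmax(fw$probs, 1e-12)
        loss <- -mean(rowSums(Y[idx, , drop = FALSE] * log(p)))
        dlogits <- (fw$probs - Y[idx, , drop = FALSE]) / B
        grads <- net_backward(decoder, fw$caches, dlogits)
        for (li in seq_along(decoder$layers)) {
          if (is.null(grads[[li]])) next
          vel[[li]]$W <- spec$momentum * vel[[li]]$W - lr * grads[[li]]$W
          vel[[li]]$b <- spec$momentum * vel[[li]]$b - lr * grads[[li]]$b
          decoder$layers[[li]]$W <- decoder$layers[[li]]$W + vel[[li]]$W
          decoder$layers[[li]]$b <- decoder$layers[[li]]$b + vel[[li]]$b
        }
        batch_no <- batch_no + 1L
        val_acc <- NA_real_
        if (!is.null(x_val) && batch_no %% spec$validate_every == 0L) {
          val_acc <- evaluate_decoder(decoder, x_val, y_val)$accuracy
        }
        log_rows[[batch_no]] <- data.frame(epoch = ep, batch = batch_no,
                                           loss = loss,
                                           val_accuracy = val_acc)
      }
    }
  })
  decoder$log <- do.call(rbind, log_rows)
  decoder$trained <- TRUE
  decoder
}

#' Predict class probabilities or labels
#'
#' @param object A trained `okn_decoder`.
#' @param x Epoch matrix (rows = epochs).
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.okn_decoder <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  p <- net_predict_probs(object, x)
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate a decoder on a labelled set
#'
#' @param decoder A trained `okn_decoder`.
#' @param x,y Epochs and labels.
#' @return List with `accuracy` and `confusion` (true x predicted counts).
#' @export
evaluate_decoder <- function(decoder, x, y) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty evaluation set", call. = FALSE)
  pred <- predict(decoder, x)
  y <- factor(y, levels = decoder$classes)
  list(accuracy = mean(pred == y),
       confusion = table(truth = y, predicted = pred))
}

#' Cross-classification between locking/labelling schemes
#'
#' Evaluates a decoder trained with one label source (e.g. button presses)
#' on epochs locked and labelled by another (e.g. OKN crossings).  Both
#' sets must share sampling rate and epoch length; with identical sources
#' this reduces to [evaluate_decoder()].
#'
#' @param trained A trained `okn_decoder`.
#' @param x_other,y_other Epochs/labels from the other scheme.
#' @return As [evaluate_decoder()].
#' @export
cross_classify <- function(trained, x_other, y_other) {
  x_other <- as.matrix(x_other)
  if (ncol(x_other) != trained$spec$input_length) {
    stop("epoch length mismatch between locking schemes", call. = FALSE)
  }
  evaluate_decoder(trained, x_other, y_other)
}

#' @export
print.okn_decoder <- function(x, ...) {
  cat(sprintf("<okn_decoder> %s mode, input 1 x %d, %d parameters%s\n",
              x$spec$conv_mode, x$spec$input_length, x$n_params,
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}
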