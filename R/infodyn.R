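# Information dynamics: delay-resolved directed information (transfer
# entropy) between ROI signals via a Gaussian-copula conditional mutual
# information estimator, and compression-based signal differentiation
# (an upper bound on Kolmogorov complexity) in sliding windows.

#' Construct ROI-averaged epochs
#'
#' @param values Epochs x time matrix of the ROI-averaged signal.
#' @param times Sample times in ms relative to the lock event.
#' @param rate Sampling rate, Hz; must match the spacing of `times`.
#' @param roi ROI name (`"front"`, `"back"`, `"left_temporal"`,
#'   `"right_temporal"`, or any label).
#' @param condition Optional condition label (`"to_INT"`/`"to_DIF"`).
#' @return An object of class `roi_epochs`.
#' @export
roi_epochs <- function(values, times, rate, roi = "front", condition = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(times))
  if (length(times) > 1L) {
    step <- unique(round(diff(times), 6))
    if (length(step) != 1L || abs(step - 1000 / rate) > 1e-6) {
      stop("`times` spacing must equal the sample period", call. = FALSE)
    }
  }
  structure(list(values = values, times = times, rate = rate, roi = roi,
                 condition = condition),
            class = "roi_epochs")
}

#' Gaussian-copula rank normalization
#'
#' Maps sample ranks to standard-normal quantiles `qnorm((rank - 0.5)/n)`.
#' The result is invariant under any strictly monotone transform of the
#' input, which is what makes the downstream information estimates robust
#' to signal amplitude distributions.  Ties are broken by stable order with
#' a warning; constant input carries no rank information and errors.
#'
#' @param x Numeric vector, at least 8 samples.
#' @return Normalized vector of the same length.
#' @export
copula_normalize <- function(x) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples", call. = FALSE)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  if (max(x) == min(x)) {
    stop("constant input: no rank information", call. = FALSE)
  }
  if (anyDuplicated(x)) warning("ties broken by stable order")
  r <- rank(x, ties.method = "first")
  stats::qnorm((r - 0.5) / n)
}

# determinant helpers on covariance entries of standardized triplets
cmi_from_moments <- function(vx, vy, vz, sxy, sxz, syz, tol = 1e-12) {
  det_xz <- vx * vz - sxz^2
  det_yz <- vy * vz - syz^2
  det_xyz <- vx * vy * vz + 2 * sxy * sxz * syz -
    vx * syz^2 - vy * sxz^2 - vz * sxy^2
  degenerate <- det_yz < tol * vy * vz
  out <- numeric(length(det_xz))
  ok <- !degenerate
  if (any(ok)) {
    out[ok] <- 0.5 * log2((det_xz[ok] * det_yz[ok]) /
                            (vz[ok] * det_xyz[ok]))
  }
  out[degenerate] <- 0 # conditioning variable identical to y: I = 0
  out
}

#' Gaussian conditional mutual information
#'
#' `I(X; Y | Z)` in bits under a Gaussian model, intended for
#' copula-normalized inputs: `I = 1/2 log2(|S_xz| |S_yz| / (|S_z| |S_xyz|))`
#' with `S` the sample covariance matrices.  With `z = NULL` the
#' unconditional mutual information is returned.  When the conditioner
#' duplicates `y` the ratio is degenerate and the information is 0 by
#' definition.  An optional small-sample bias correction subtracts the
#' expected log-determinant bias of Wishart estimates (off by default).
#'
#' @param x,y,z Equal-length numeric vectors (n >= 16); `z` optional.
#' @param bias_correct Apply the Gaussian small-sample bias correction.
#' @return Information in bits (non-negative up to numerical tolerance).
#' @export
gaussian_cmi <- function(x, y, z = NULL, bias_correct = FALSE) {
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples", call. = FALSE)
  if (length(y) != n || (!is.null(z) && length(z) != n)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  cx <- x - mean(x); cy <- y - mean(y)
  vx <- sum(cx^2) / (n - 1); vy <- sum(cy^2) / (n - 1)
  sxy <- sum(cx * cy) / (n - 1)
  if (vx <= 0 || vy <= 0) stop("singular covariance", call. = FALSE)
  if (is.null(z)) {
    r2 <- sxy^2 / (vx * vy)
    if (r2 >= 1) stop("singular covariance", call. = FALSE)
    mi <- -0.5 * log2(1 - r2)
    if (bias_correct) mi <- mi - wishart_logdet_bias(n, c(1, 1, -2)) / 2
    return(mi)
  }
  cz <- z - mean(z)
  vz <- sum(cz^2) / (n - 1)
  if (vz <= 0) stop("singular covariance (constant conditioner)", call. = FALSE)
  sxz <- sum(cx * cz) / (n - 1)
  syz <- sum(cy * cz) / (n - 1)
  i <- cmi_from_moments(vx, vy, vz, sxy, sxz, syz)
  if (!is.finite(i)) stop("singular covariance", call. = FALSE)
  if (bias_correct) i <- i - wishart_logdet_bias(n, c(2, 2, -1, -3)) / 2
  i
}

# E[log det Shat] - log det S = sum_i psi((n-i)/2) - p log((n-1)/2) for a
# p-variate Wishart; `ps` holds signed dimensions entering the CMI ratio.
wishart_logdet_bias <- function(n, ps) {
  one <- function(p) {
    if (p == 0) return(0)
    s <- sign(p); p <- abs(p)
    s * (sum(digamma((n - seq_len(p)) / 2)) - p * log((n - 1) / 2))
  }
  sum(vapply(ps, one, numeric(1))) / log(2)
}

rank_norm_cols <- function(M) {
  n <- nrow(M)
  R <- apply(M, 2L, rank, ties.method = "first")
  matrix(stats::qnorm((R - 0.5) / n), n, ncol(M))
}

#' Delay-resolved directed information between two ROI signal sets
#'
#' For each time `t` and delay `tau`, estimates
#' `I(Y_t ; X_{t - tau} | Y_{t - tau})` across epochs: the information the
#' past of the sender `X` carries about the present of the receiver `Y`
#' over and above the receiver's own past.  Each triplet is
#' copula-normalized across epochs before the Gaussian CMI is evaluated, so
#' the map is invariant under monotone amplitude transforms of either
#' signal.  Cells with `t - tau` before the epoch start are `NA`.
#'
#' @param source,target [roi_epochs()] with identical epochs/times/rate.
#' @param delays Delays in ms (sample multiples), default 0-500 ms in 4 ms
#'   steps.
#' @param times Optional subset of evaluation times (ms); defaults to all
#'   epoch times.
#' @param bias_correct Subtract the expected Wishart log-determinant bias
#'   (a constant offset at fixed epoch count) from the whole map.  Off by
#'   default; condition differences cancel the bias regardless.
#' @return A `delay_time_map`: list with `values` (delays x times, bits),
#'   `delays`, `times`, `direction`, `condition`, `n_epochs`.
#' @export
directed_information <- function(source, target, delays = seq(0, 500, by = 4),
                                 times = NULL, bias_correct = FALSE) {
  stopifnot(inherits(source, "roi_epochs"), inherits(target, "roi_epochs"))
  if (!identical(dim(source$values), dim(target$values)) ||
      !isTRUE(all.equal(source$times, target$times)) ||
      source$rate != target$rate) {
    stop("source and target must share epochs, times and rate", call. = FALSE)
  }
  n <- nrow(source$values)
  if (n < 16L) stop("need at least 16 epochs", call. = FALSE)
  rate <- source$rate
  lag_samp <- delays * rate / 1000
  if (any(abs(lag_samp - round(lag_samp)) > 1e-8)) {
    stop("`delays` must be multiples of the sample period", call. = FALSE)
  }
  lag_samp <- as.integer(round(lag_samp))
  t_all <- source$times
  t_eval <- times %||% t_all
  ti <- match(round(t_eval, 6), round(t_all, 6))
  if (anyNA(ti)) stop("`times` must be a subset of the epoch times", call. = FALSE)

  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  v <- sum(q^2) / (n - 1) # variance of the fixed quantile grid, all columns
  vals <- matrix(NA_real_, length(delays), length(ti))
  for (d in seq_along(delays)) {
    L <- lag_samp[d]
    ok <- which(ti - L >= 1L)
    if (!length(ok)) next
    ii <- ti[ok]
    Gy <- rank_norm_cols(target$values[, ii, drop = FALSE])
    Gx <- rank_norm_cols(source$values[, ii - L, drop = FALSE])
    Gz <- rank_norm_cols(target$values[, ii - L, drop = FALSE])
    sxy <- colSums(Gx * Gy) / (n - 1)
    sxz <- colSums(Gx * Gz) / (n - 1)
    syz <- colSums(Gy * Gz) / (n - 1)
    vals[d, ok] <- cmi_from_moments(rep(v, length(ok)), rep(v, length(ok)),
                                    rep(v, length(ok)), sxy, sxz, syz)
  }
  if (bias_correct) {
    # the Wishart log-determinant bias is a constant offset at fixed n
    vals <- vals - wishart_logdet_bias(n, c(2, 2, -1, -3)) / 2
  }
  structure(list(values = vals, delays = delays, times = t_eval,
                 direction = paste0(source$roi, "->", target$roi),
                 condition = target$condition %||% source$condition,
                 n_epochs = n),
            class = "delay_time_map")
}

#' Symbolize a signal window
#'
#' The amplitude range of the window is divided into `n_symbols`
#' equal-width bins; each sample maps to its bin index (the maximum lands
#' in the top bin).  The symbols are returned as raw bytes ready for
#' compression, which makes the representation affine-invariant: any
#' `a * x + b` (a > 0) of the window gives identical symbols.
#'
#' @param window_values Numeric vector; needs >= 2 distinct values,
#'   otherwise all symbols are 0 with a warning.
#' @param n_symbols Number of amplitude bins (<= 256).
#' @return Raw vector, one byte per sample.
#' @export
symbolize <- function(window_values, n_symbols = 32) {
  if (!length(window_values)) stop("empty window", call. = FALSE)
  stopifnot(n_symbols >= 2, n_symbols <= 256)
  mn <- min(window_values); mx <- max(window_values)
  if (mx == mn) {
    warning("constant window: all symbols identical")
    return(as.raw(rep(0L, length(window_values))))
  }
  b <- floor((window_values - mn) / (mx - mn) * n_symbols)
  b[b >= n_symbols] <- n_symbols - 1
  as.raw(b)
}

# fixed zlib wrapper overhead (2-byte header + 4-byte Adler-32 trailer)
ZLIB_OVERHEAD <- 6L

#' Compression-ratio complexity of a signal window
#'
#' The window is symbolized ([symbolize()]) and DEFLATE-compressed at the
#' default level (6); the complexity is compressed bytes divided by
#' original bytes, with the fixed container wrapper bytes excluded so
#' ratios are comparable across window lengths.  Lower values mean a more
#' redundant (less differentiated) signal; values can exceed 1 for short
#' incompressible windows.
#'
#' @inheritParams symbolize
#' @return Compression ratio (dimensionless, > 0).
#' @export
k_complexity <- function(window_values, n_symbols = 32) {
  sym <- symbolize(window_values, n_symbols)
  comp <- memCompress(sym, type = "gzip")
  max(length(comp) - ZLIB_OVERHEAD, 1L) / length(sym)
}

#' Sliding-window complexity time course
#'
#' [k_complexity()] in a sliding window (default 100 ms window, 4 ms step)
#' over each epoch, averaged across epochs.  The number of windows is
#' `floor((L - w) / s) + 1` for an epoch of `L` samples.
#'
#' @param epochs A [roi_epochs()].
#' @param window,step Window length and step in ms.
#' @param n_symbols Amplitude bins per window.
#' @return A `complexity_series`: `values` (mean ratio per window centre),
#'   `per_epoch` (epochs x windows), `centers` (ms), `window`, `step`,
#'   `n_symbols`.
#' @export
complexity_timecourse <- function(epochs, window = 100, step = 4,
                                  n_symbols = 32) {
  stopifnot(inherits(epochs, "roi_epochs"))
  rate <- epochs$rate
  w <- as.integer(round(window / 1000 * rate))
  s <- max(1L, as.integer(round(step / 1000 * rate)))
  L <- ncol(epochs$values)
  if (w < 2L) stop("window shorter than 2 samples", call. = FALSE)
  if (w > L) stop("window longer than the epoch", call. = FALSE)
  n_win <- (L - w) %/% s + 1L
  starts <- (seq_len(n_win) - 1L) * s + 1L
  per <- matrix(NA_real_, nrow(epochs$values), n_win)
  for (e in seq_len(nrow(epochs$values))) {
    row <- epochs$values[e, ]
    per[e, ] <- vapply(starts, function(i) {
      suppressWarnings(k_complexity(row[i:(i + w - 1L)], n_symbols))
    }, numeric(1))
  }
  centers <- epochs$times[starts] + (w - 1L) / 2 * (1000 / rate)
  structure(list(values = colMeans(per), per_epoch = per, centers = centers,
                 window = window, step = step, n_symbols = n_symbols,
                 roi = epochs$roi, condition = epochs$condition),
            class = "complexity_series")
}

#' @export
print.delay_time_map <- function(x, ...) {
  cat(sprintf("<delay_time_map> %s%s: %d delays x %d times, %d epochs\n",
              x$direction,
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              length(x$delays), length(x$times), x$n_epochs))
  invisible(x)
}

#' @export
print.complexity_series <- function(x, ...) {
  cat(sprintf("<complexity_series> %s: %d windows (%g ms / %g ms, %d symbols)\n",
              x$roi, length(x$values), x$window, x$step, x$n_symbols))
  invisible(x)
}
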