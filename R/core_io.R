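# EEG preprocessing (resampling, band-pass, notch, average reference),
# channel and epoch rejection, event filtering, ROI definitions and
# averaging, and delimited-text I/O.  ICA and spherical-spline channel
# interpolation are deliberately not part of this pipeline; it accepts
# already-cleaned or synthetic signals.

#' Construct an EEG recording
#'
#' @param data Channels x samples matrix (uV); row names are channel names.
#' @param rate Sampling rate, Hz.
#' @param ch_names Channel names (defaults to row names).
#' @param start_time Time of the first sample, seconds.
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, ch_names = rownames(data),
                          start_time = 0) {
  data <- as.matrix(data)
  stop_if_not_positive(rate, "rate")
  ch_names <- ch_names %||% paste0("ch", seq_len(nrow(data)))
  if (anyDuplicated(ch_names)) stop("channel names must be unique", call. = FALSE)
  rownames(data) <- ch_names
  structure(list(data = data, rate = rate, ch_names = ch_names,
                 start_time = start_time),
            class = "eeg_recording")
}

#' Default ROI montage
#'
#' Six-channel bilateral frontal, parietal, left-temporal and
#' right-temporal clusters in 10-20 nomenclature.  The exact cluster
#' identities of the original recordings are published only as a figure;
#' these defaults are a plausible reconstruction and fully editable —
#' pass your own named list of channel vectors anywhere a montage is
#' accepted.
#'
#' @param n_per_roi Channels per ROI (<= 6).
#' @return Named list with `front`, `back`, `left_temporal`,
#'   `right_temporal` character vectors (pairwise disjoint).
#' @export
roi_definitions <- function(n_per_roi = 6) {
  stopifnot(n_per_roi >= 1, n_per_roi <= 6)
  lapply(list(front = c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4"),
              back = c("P1", "P2", "P3", "P4", "PO3", "PO4"),
              left_temporal = c("FT7", "FC5", "T7", "C5", "TP7", "CP5"),
              right_temporal = c("FT8", "FC6", "T8", "C6", "TP8", "CP6")),
         utils::head, n_per_roi)
}

#' Preprocess a raw EEG recording
#'
#' Resamples to `target_rate` (polyphase FIR), band-passes (zero-phase
#' Butterworth, default 1-100 Hz), notch-filters the line frequency
#' (zero-phase band-stop around 50 Hz) and re-references every sample to
#' the average over channels, in that order.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Output rate, Hz.
#' @param band Band-pass edges, Hz.
#' @param notch Line frequency to suppress, Hz (`NULL` to skip).
#' @param notch_width Half-width of the stop band, Hz.
#' @return The preprocessed `eeg_recording`.
#' @export
preprocess_eeg <- function(rec, target_rate = 250, band = c(1, 100),
                           notch = 50, notch_width = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate < target_rate) stop("recording rate below target", call. = FALSE)
  x <- rec$data
  if (rec$rate != target_rate) {
    frac <- rational_approx(target_rate / rec$rate)
    x <- t(apply(x, 1L, function(ch) {
      as.numeric(signal::resample(ch, frac[1L], frac[2L]))
    }))
    rec$rate <- target_rate
  }
  nyq <- rec$rate / 2
  if (band[2] >= nyq) stop("band edge at or above Nyquist", call. = FALSE)
  bp <- signal::butter(4, band / nyq, type = "pass")
  pad <- as.integer(ceiling(8 * rec$rate / band[1]))
  x <- t(apply(x, 1L, function(ch) filtfilt_pad(bp, ch, pad)))
  if (!is.null(notch) && notch < nyq) {
    ns <- signal::butter(2, c(notch - notch_width, notch + notch_width) / nyq,
                         type = "stop")
    x <- t(apply(x, 1L, function(ch) filtfilt_pad(ns, ch, rec$rate)))
  }
  x <- sweep(x, 2L, colMeans(x), "-") # average reference
  rownames(x) <- rec$ch_names
  rec$data <- x
  rec
}

# smallest integer ratio p/q approximating r (for resampling)
rational_approx <- function(r, max_den = 1024L) {
  best <- c(1L, 1L)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      err <- e
      best <- c(as.integer(p), q)
      if (e < 1e-12) break
    }
  }
  best
}

#' Flag channels with outlying variance
#'
#' Channel variances are z-scored across channels; channels beyond
#' `sd_bounds` SDs are flagged for rejection.  Interpolation of flagged
#' channels is out of scope here — the drop list feeds an external
#' interpolation step.
#'
#' @param rec An [eeg_recording()] (>= 8 channels).
#' @param sd_bounds Symmetric z threshold.
#' @return List with `keep`, `drop` (channel names) and `z` (named scores).
#' @export
reject_channels <- function(rec, sd_bounds = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 8L) stop("need at least 8 channels", call. = FALSE)
  v <- apply(rec$data, 1L, stats::var)
  s <- stats::sd(v)
  z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  names(z) <- rec$ch_names
  drop <- rec$ch_names[abs(z) > sd_bounds]
  list(keep = setdiff(rec$ch_names, drop), drop = drop, z = z)
}

#' Filter switch events for epoching
#'
#' Removes (1) switches whose predecessor in the stream occurred less than
#' `min_interval` seconds earlier, (2) same-direction repetitions, and
#' (3) events whose epoch window contains another event (more than one
#' response per epoch).  Rules are applied in that order and each removal
#' is attributed to the first rule that fires.
#'
#' @param events Time-sorted data frame with `time` and `direction`.
#' @param min_interval Minimum inter-switch interval, seconds.
#' @param window Epoch window in ms around each event.
#' @return List with `events` (retained rows) and `log` (counts per rule).
#' @export
filter_switch_events <- function(events, min_interval = 2,
                                 window = c(-2000, 500)) {
  stopifnot(is.data.frame(events), all(c("time", "direction") %in% names(events)))
  if (is.unsorted(events$time)) stop("events must be time-sorted", call. = FALSE)
  n <- nrow(events)
  reason <- rep(NA_character_, n)
  if (n > 1L) {
    gap_bad <- c(FALSE, diff(events$time) < min_interval)
    reason[gap_bad & is.na(reason)] <- "interval"
    rep_bad <- c(FALSE, events$direction[-1L] == events$direction[-n])
    reason[rep_bad & is.na(reason)] <- "repetition"
    for (i in seq_len(n)) {
      if (!is.na(reason[i])) next
      lo <- events$time[i] + window[1] / 1000
      hi <- events$time[i] + window[2] / 1000
      others <- events$time[-i]
      if (any(others >= lo & others <= hi)) reason[i] <- "multi_response"
    }
  }
  keep <- is.na(reason)
  list(events = events[keep, , drop = FALSE],
       log = c(total = n, retained = sum(keep),
               interval = sum(reason == "interval", na.rm = TRUE),
               repetition = sum(reason == "repetition", na.rm = TRUE),
               multi_response = sum(reason == "multi_response", na.rm = TRUE)))
}

#' Cut epochs around events and reject artifacts
#'
#' Epochs span `window` ms around each event (half-open sample window).
#' An epoch is rejected if any channel sample exceeds `amp_bound` uV in
#' magnitude, or if the magnitude of the least-squares linear fit's total
#' rise over the epoch exceeds `slope_bound` uV on any channel.  Events too
#' close to the recording edges are skipped and logged.  Rejections are
#' attributed to the first failing rule.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param events Data frame with `time` (s) and `direction`.
#' @param window Epoch window, ms.
#' @param amp_bound Amplitude bound, uV.
#' @param slope_bound Slope bound, uV over the epoch.
#' @return An `epoch_set`: `data` (epochs x channels x time), `times` (ms),
#'   `rate`, `labels`, `events`, and a rejection `log`.
#' @export
epoch_and_reject <- function(rec, events, window = c(-2000, 500),
                             amp_bound = 150, slope_bound = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  rel <- seq(as.integer(round(window[1] / 1000 * rate)),
             as.integer(round(window[2] / 1000 * rate)))
  nT <- length(rel)
  n_samp <- ncol(rec$data)
  tc <- rel - mean(rel)
  denom <- sum(tc^2)
  keep_rows <- list()
  labels <- character(0)
  kept_events <- list()
  log <- c(total = nrow(events), retained = 0L, edge = 0L, amplitude = 0L,
           slope = 0L)
  for (i in seq_len(nrow(events))) {
    c0 <- as.integer(round((events$time[i] - rec$start_time) * rate)) + 1L
    idx <- c0 + rel
    if (idx[1L] < 1L || idx[nT] > n_samp) {
      log["edge"] <- log["edge"] + 1L
      next
    }
    ep <- rec$data[, idx, drop = FALSE]
    if (any(abs(ep) > amp_bound)) {
      log["amplitude"] <- log["amplitude"] + 1L
      next
    }
    rise <- abs((ep %*% tc) / denom) * (nT - 1L)
    if (any(rise > slope_bound)) {
      log["slope"] <- log["slope"] + 1L
      next
    }
    keep_rows[[length(keep_rows) + 1L]] <- ep
    labels <- c(labels, as.character(events$direction[i]))
    kept_events[[length(kept_events) + 1L]] <- events[i, , drop = FALSE]
  }
  log["retained"] <- length(keep_rows)
  n_keep <- length(keep_rows)
  data <- array(NA_real_, c(n_keep, nrow(rec$data), nT),
                dimnames = list(NULL, rec$ch_names, NULL))
  for (k in seq_len(n_keep)) data[k, , ] <- keep_rows[[k]]
  structure(list(data = data, times = rel / rate * 1000, rate = rate,
                 labels = labels,
                 events = if (n_keep) do.call(rbind, kept_events) else
                   events[0, , drop = FALSE],
                 log = log),
            class = "epoch_set")
}

#' Average an epoch set over an ROI
#'
#' Unweighted mean across the ROI's channels for every epoch and sample.
#'
#' @param epochs An [epoch_and_reject()] `epoch_set`.
#' @param roi Character vector of channel names, or the name of an ROI in
#'   `montage`.
#' @param montage Named list of ROIs (default [roi_definitions()]).
#' @param condition Optional condition filter on epoch labels.
#' @return A [roi_epochs()].
#' @export
roi_average <- function(epochs, roi, montage = roi_definitions(),
                        condition = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  roi_name <- if (is.character(roi) && length(roi) == 1L &&
                  roi %in% names(montage)) roi else "custom"
  chans <- if (identical(roi_name, "custom")) roi else montage[[roi]]
  missing <- setdiff(chans, dimnames(epochs$data)[[2L]])
  if (length(missing)) {
    stop("missing ROI channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sel <- seq_len(dim(epochs$data)[1L])
  if (!is.null(condition)) sel <- which(epochs$labels == condition)
  sub <- epochs$data[sel, chans, , drop = FALSE]
  vals <- apply(sub, c(1L, 3L), mean)
  roi_epochs(vals, times = epochs$times, rate = epochs$rate,
             roi = if (identical(roi_name, "custom")) paste(chans, collapse = "+")
             else roi_name,
             condition = condition)
}

#' Read eye-tracker samples / events from delimited text
#'
#' `read_eye_samples` expects columns `time` (s) and `x` (position); the
#' sampling rate is inferred from the median time step.  `read_eye_events`
#' expects `onset`, `offset` and `type` (`"blink"`/`"saccade"`), as
#' exported by EyeLink-style ASC conversions.
#'
#' @param path Input path (tab- or whitespace-delimited with header).
#' @return `read_eye_samples`: an [oculomotor_trace()];
#'   `read_eye_events`: a data frame.
#' @export
read_eye_samples <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("time", "x") %in% names(d)))
  rate <- 1 / stats::median(diff(d$time))
  oculomotor_trace(d$x, rate = round(rate), start_time = d$time[1L])
}

#' @rdname read_eye_samples
#' @export
read_eye_events <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("onset", "offset", "type") %in% names(d)))
  d
}

#' Write / read switch events as delimited text
#'
#' Tab-separated columns `time`, `direction`, `source`.
#'
#' @param events Data frame of switch events.
#' @param path File path.
#' @export
write_switch_events <- function(events, path) {
  utils::write.table(events[, c("time", "direction", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_switch_events
#' @export
read_switch_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L], x$rate))
  cat("  rejection log:", paste(names(x$log), x$log, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.roi_epochs <- function(x, ...) {
  cat(sprintf("<roi_epochs> %s%s: %d epochs x %d samples @ %g Hz\n",
              x$roi, if (is.null(x$condition)) "" else
                paste0(" [", x$condition, "]"),
              nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}
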