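#' Multichannel EEG recording
#'
#' Container for a uniformly sampled multichannel voltage time series.
#' Channels are rows and time is columns; voltages are stored in microvolts
#' (muV) throughout the package.  Sample indices in the API are native R
#' 1-based indices; times are in seconds and converted to samples with
#' `round(t * fs)` (round-half-to-even, R's default).
#'
#' @param samples numeric matrix, channels x time, muV.
#' @param fs sampling rate, Hz (> 0).
#' @param channel_labels character vector of unique channel names
#'   (10-20-system labels such as "C3", "CZ" for scalp channels).
#' @param start_time recording start, seconds (default 0).
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, channel_labels, start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(channel_labels) != nrow(samples)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(samples), ")")
  }
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (any(!is.finite(samples))) stop("recording contains NaN/Inf samples; refusing to ingest")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Extract one channel by label
#' @param rec an `eeg_recording`.
#' @param label channel label.
#' @return numeric vector of samples (muV).
#' @export
get_channel <- function(rec, label) {
  i <- match(label, rec$channel_labels)
  if (is.na(i)) stop("unknown channel label: '", label, "'")
  rec$samples[i, ]
}

set_channel <- function(rec, label, x) {
  i <- match(label, rec$channel_labels)
  if (is.na(i)) stop("unknown channel label: '", label, "'")
  stopifnot(length(x) == ncol(rec$samples))
  rec$samples[i, ] <- x
  rec
}

#' Event marker series
#'
#' @param times event times in seconds, strictly increasing.
#' @param label event name, e.g. `"button_press"`.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times, label = "button_press") {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) stop("event times must be strictly increasing")
  structure(list(times = times, label = label), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> '%s': %d events", x$label, length(x$times)))
  if (length(x$times)) cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Bipolar derivation of two channels
#'
#' Returns anode minus cathode, sample-aligned — e.g. the left central
#' dipole C3-CZ used for motor gamma.  A bipolar derivation cancels
#' far-field activity common to both electrodes.
#'
#' @param rec an `eeg_recording`.
#' @param anode,cathode channel labels.
#' @return numeric vector `anode - cathode`, same length as the recording.
#' @export
derive_bipolar <- function(rec, anode, cathode) {
  if (identical(anode, cathode)) stop("anode and cathode must differ")
  get_channel(rec, anode) - get_channel(rec, cathode)
}

#' Cut fixed-length epochs around events
#'
#' Each epoch spans `[t - pre_s, t + post_s)` around its event time `t` and
#' has exactly `round((pre_s + post_s) * fs)` samples.  Events whose window
#' would cross a recording edge are dropped with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param events an `event_series`.
#' @param pre_s,post_s window extent before/after the event, seconds (>= 0,
#'   not both zero).
#' @return list of epochs; each has `samples` (channels x time matrix),
#'   `event_time` (s), `start_index` (1-based first sample) and `n` (length).
#' @export
segment_epochs <- function(rec, events, pre_s, post_s) {
  stopifnot(pre_s >= 0, post_s >= 0)
  if (pre_s + post_s <= 0) stop("epoch window has zero length (pre_s + post_s must be > 0)")
  len <- as.integer(round((pre_s + post_s) * rec$fs))
  n <- n_samples(rec)
  out <- list()
  dropped <- 0L
  for (t in events$times) {
    start <- round((t - pre_s - rec$start_time) * rec$fs) + 1L
    if (start < 1L || start + len - 1L > n) {
      dropped <- dropped + 1L
      next
    }
    idx <- start:(start + len - 1L)
    out[[length(out) + 1L]] <- list(samples = rec$samples[, idx, drop = FALSE],
                                    event_time = t, start_index = start, n = len)
  }
  if (dropped > 0L) warning(dropped, " event(s) too close to recording edges were dropped")
  if (!length(out)) stop("no usable events: all epochs fall outside the recording")
  out
}
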