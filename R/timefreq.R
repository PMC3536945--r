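# Sliding Hanning-windowed FFT amplitude analysis.  Default window lengths
# follow the sampling rate: 512 points (256 ms) at 2,000 Hz and 2,048
# points (409.6 ms) at 5,000 Hz, with windows cut every 5 ms.  Amplitudes
# use coherent-gain normalisation (2 |FFT| / sum(window), so an on-bin
# unit-amplitude sinusoid reads 1 muV) and are then divided by the bin
# width to give a bin-width-independent muV/Hz scale.

#' Default FFT window length for a sampling rate
#'
#' 512 samples at 2,000 Hz (256 ms) and 2,048 samples at 5,000 Hz
#' (409.6 ms); otherwise the power of two closest to 256 ms.
#'
#' @param fs sampling rate, Hz.
#' @return window length in samples.
#' @export
default_window_samples <- function(fs) {
  if (fs == 2000) return(512L)
  if (fs == 5000) return(2048L)
  as.integer(2^round(log2(0.256 * fs)))
}

#' Sliding-window FFT amplitude map
#'
#' Cuts windows of `window_samples` points every `step_s` seconds,
#' multiplies each by a Hanning window and takes the FFT amplitude.  Time
#' stamps are window *centres*, so selecting "0-250 ms after an event"
#' means windows whose centres fall in that interval.
#'
#' @param x single-channel signal, muV (e.g. a bipolar derivation).
#' @param fs sampling rate, Hz.
#' @param window_samples FFT window length; default per
#'   [default_window_samples()].
#' @param step_s hop between window starts, seconds (default 0.005).
#' @param fmax keep only frequency bins up to this, Hz (default Nyquist);
#'   bounds memory on long recordings.
#' @param start_time time of the first sample, seconds.
#' @param derivation optional label stored with the map.
#' @return a `tf_map`: `amplitudes` (time-steps x freq-bins, muV/Hz),
#'   `times` (window-centre s), `freqs` (Hz), `window_samples`, `fs`.
#' @export
sliding_fft_amplitude <- function(x, fs, window_samples = default_window_samples(fs),
                                  step_s = 0.005, fmax = fs / 2,
                                  start_time = 0, derivation = NULL) {
  n <- length(x)
  win <- as.integer(window_samples)
  if (win > n) stop("window (", win, " samples) longer than signal (", n, ")")
  step <- max(1L, round(step_s * fs))
  starts <- seq.int(1L, n - win + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(win - 1L)) / (win - 1L)))   # symmetric Hanning
  cg <- sum(w)
  nb <- win %/% 2L + 1L
  freqs <- (0:(nb - 1L)) * fs / win
  keep <- freqs <= fmax
  binw <- fs / win
  amps <- matrix(0, nrow = length(starts), ncol = sum(keep))
  # chunked so the windowed matrix stays modest on long recordings
  chunk <- max(1L, floor(4e6 / win))
  for (c0 in seq.int(1L, length(starts), by = chunk)) {
    c1 <- min(c0 + chunk - 1L, length(starts))
    idx <- outer(0:(win - 1L), starts[c0:c1], `+`)
    M <- matrix(x[idx], nrow = win) * w
    Fm <- stats::mvfft(M)[seq_len(nb), , drop = FALSE]
    A <- 2 * Mod(Fm) / cg
    A[1L, ] <- A[1L, ] / 2                       # DC not doubled
    if (win %% 2L == 0L) A[nb, ] <- A[nb, ] / 2  # Nyquist not doubled
    amps[c0:c1, ] <- t(A[keep, , drop = FALSE]) / binw
  }
  structure(list(amplitudes = amps,
                 times = start_time + (starts - 1L + (win - 1L) / 2) / fs,
                 freqs = freqs[keep], window_samples = win, fs = fs,
                 derivation = derivation),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d time-steps x %d freq-bins (%.1f-%.1f Hz, bin %.3g Hz), window %d samples\n",
              nrow(x$amplitudes), ncol(x$amplitudes), min(x$freqs), max(x$freqs),
              x$fs / x$window_samples, x$window_samples))
  invisible(x)
}

#' Mean band amplitude over time
#'
#' Arithmetic mean of the map's amplitude over all frequency bins with
#' `f_lo <= f <= f_hi` (both edges inclusive), per time step.  The bands
#' used for motor gamma work are 65-85, 60-130, 85-130 and 65-130 Hz.
#'
#' @param map a `tf_map` from [sliding_fft_amplitude()].
#' @param f_lo,f_hi band edges, Hz.
#' @return numeric vector (one value per time step), muV/Hz.
#' @export
band_amplitude <- function(map, f_lo, f_hi) {
  sel <- map$freqs >= f_lo & map$freqs <= f_hi
  if (!any(sel)) stop("no frequency bins inside [", f_lo, ", ", f_hi, "] Hz")
  rowMeans(map$amplitudes[, sel, drop = FALSE])
}

# Fast path for a single band: the STFT at each retained bin equals a
# correlation of the signal with the modulated Hanning kernel, computed by
# FFT convolution over the whole recording at once instead of per-window
# mvfft.  Identical normalisation to sliding_fft_amplitude.
.stft_kernels <- new.env(parent = emptyenv())

stft_band_series <- function(x, fs, window_samples, step_s = 0.005,
                             f_lo, f_hi, start_time = 0) {
  n <- length(x)
  win <- as.integer(window_samples)
  if (win > n) stop("window longer than signal")
  step <- max(1L, round(step_s * fs))
  starts <- seq.int(1L, n - win + 1L, by = step)
  nb <- win %/% 2L + 1L
  freqs <- (0:(nb - 1L)) * fs / win
  bins <- which(freqs >= f_lo & freqs <= f_hi)
  if (!length(bins)) stop("no frequency bins inside [", f_lo, ", ", f_hi, "] Hz")
  m <- stats::nextn(n + win, 2)
  key <- paste(win, m, paste(bins, collapse = ","), sep = "|")
  K <- .stft_kernels[[key]]
  if (is.null(K)) {
    w <- 0.5 * (1 - cos(2 * pi * (0:(win - 1L)) / (win - 1L)))
    K <- lapply(bins, function(b) {
      h <- w * exp(-2i * pi * (b - 1L) * (0:(win - 1L)) / win)
      stats::fft(c(rev(h), complex(real = numeric(m - win))))
    })
    attr(K, "cg") <- sum(w)
    .stft_kernels[[key]] <- K
  }
  cg <- attr(K, "cg")
  X <- stats::fft(c(x, numeric(m - n)))
  binw <- fs / win
  acc <- numeric(length(starts))
  for (bi in seq_along(bins)) {
    conv <- stats::fft(X * K[[bi]], inverse = TRUE) / m
    amp <- 2 * Mod(conv[starts + win - 1L]) / cg
    if (bins[bi] == 1L) amp <- amp / 2
    if (win %% 2L == 0L && bins[bi] == nb) amp <- amp / 2
    acc <- acc + amp / binw
  }
  list(series = acc / length(bins),
       times = start_time + (starts - 1L + (win - 1L) / 2) / fs)
}

# Mean of a band series over time stamps within [t_lo, t_hi] (inclusive).
band_window_mean <- function(series, times, t_lo, t_hi) {
  sel <- times >= t_lo & times <= t_hi
  if (!any(sel)) return(NA_real_)
  mean(series[sel])
}

#' Serialise a time-frequency map
#'
#' Writes the amplitude matrix as a plain-text table and a JSON sidecar
#' with times, frequencies and window metadata.
#'
#' @param map a `tf_map`.
#' @param path base path; `<path>.txt` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_tf_map <- function(map, path) {
  utils::write.table(format(map$amplitudes, digits = 8, trim = TRUE),
                     paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(times = map$times, freqs = map$freqs,
                            window_samples = map$window_samples, fs = map$fs,
                            derivation = map$derivation),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
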