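#' Amplitude reduction implied by a power reduction
#'
#' Band power is the square of band amplitude, so a fractional power
#' reduction `p` corresponds to an amplitude reduction `1 - sqrt(1 - p)`.
#' For example a 33% power reduction is an 18% amplitude reduction and a
#' 93% power reduction is a 73% amplitude reduction.
#'
#' @param power_reduction fractional power reduction in `[0, 1]`.
#' @return fractional amplitude reduction in `[0, 1]`.
#' @examples
#' round(100 * amp_reduction_from_power(0.33))  # 18
#' round(100 * amp_reduction_from_power(0.93))  # 73
#' @export
amp_reduction_from_power <- function(power_reduction) {
  stopifnot(is.numeric(power_reduction), all(power_reduction >= 0), all(power_reduction <= 1))
  1 - sqrt(1 - power_reduction)
}

#' Power reduction implied by an amplitude reduction
#'
#' Inverse of [amp_reduction_from_power()].
#'
#' @param amp_reduction fractional amplitude reduction in `[0, 1]`.
#' @return fractional power reduction in `[0, 1]`.
#' @export
power_reduction_from_amp <- function(amp_reduction) {
  stopifnot(is.numeric(amp_reduction), all(amp_reduction >= 0), all(amp_reduction <= 1))
  1 - (1 - amp_reduction)^2
}

# Analytic signal z = x + i*H(x) via the one-sided FFT construction.
# Im(z) lags Re(z) by a quarter cycle for a positive-frequency component.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic-signal transform")
  # reflect-pad to a highly composite length: R's mixed-radix FFT is
  # quadratic on prime lengths
  m <- stats::nextn(n, 2)
  if (m > n) {
    pad <- min(m - n, n - 1L)
    xp <- c(x, rev(x[(n - pad):(n - 1L)]), numeric(m - n - pad))
  } else xp <- x
  X <- stats::fft(xp)
  h <- numeric(m)
  h[c(1L, m / 2L + 1L)] <- 1
  h[2:(m / 2L)] <- 2
  (stats::fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

# Zero-phase FIR filtering: convolve with symmetric (linear-phase) taps via
# FFT and remove the group delay (length(b) must be odd).  Edges are padded
# by reflection so transients do not bleed into the analysis span.
fir_zero_phase <- function(x, b) {
  nb <- length(b)
  if (nb %% 2L == 0L) stop("zero-phase FIR needs an odd number of taps")
  half <- (nb - 1L) / 2L
  n <- length(x)
  pad <- min(half, n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp) + nb - 1L
  nfft <- stats::nextn(m, 2)
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  B <- stats::fft(c(b, numeric(nfft - nb)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
  y[(pad + half + 1L):(pad + half + n)]
}

# Band-pass FIR taps centred on [f_lo, f_hi] Hz; transition width trans Hz.
fir_bandpass_taps <- function(fs, f_lo, f_hi, trans = 1) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_hi < fs / 2)
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2L == 1L) ord <- ord + 1L
  as.numeric(signal::fir1(ord, c(f_lo, f_hi) / (fs / 2), type = "pass"))
}

fir_highpass_taps <- function(fs, cutoff, trans = 5) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2L == 1L) ord <- ord + 1L
  as.numeric(signal::fir1(ord, cutoff / (fs / 2), type = "high"))
}

#' Zero-phase high-pass filter
#'
#' Linear-phase FIR high-pass applied forwards with the group delay removed,
#' so filtered features stay time-aligned with the input.  Used to prepare
#' the detection copy of a signal (default 10 Hz cutoff) without delaying
#' spike latencies.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass cutoff, Hz.
#' @return filtered signal, same length as `x`.
#' @export
highpass_zero_phase <- function(x, fs, cutoff = 10) {
  fir_zero_phase(x, fir_highpass_taps(fs, cutoff))
}

# Mean band amplitude (root mean square spectral content) of x in [f_lo,f_hi],
# via the periodogram; used by tests and score_correction for quick band power
# book-keeping on whole signals.
band_rms <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  m <- stats::nextn(n, 2)     # zero-pad: energy is preserved and the FFT
  X <- stats::fft(c(x, numeric(m - n)))   # stays fast on any length
  f <- (seq_len(m) - 1L) * fs / m
  sel <- f >= f_lo & f <= f_hi & f <= fs / 2
  sqrt(2 * sum(Mod(X[sel])^2) / (as.numeric(m) * n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
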