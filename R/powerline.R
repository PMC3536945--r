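# Power-line (mains) interference cancellation.  The fundamental is
# band-pass extracted from a noise reference, its quadrature obtained from
# the analytic signal (a pi/2 phase shift at the carrier), harmonics are
# built from the pair by the angle-addition recursion
#   sin((k+1)t) = sin(kt)cos(t) + cos(kt)sin(t)
#   cos((k+1)t) = cos(kt)cos(t) - sin(kt)sin(t)
# and each EEG channel is regressed on the basis; the fitted mains part is
# subtracted.  Regression makes the method robust to per-channel amplitude
# and phase differences of the interference.

#' Extract the mains fundamental as a unit quadrature pair
#'
#' Band-passes the noise reference around `f0`, normalises to unit
#' amplitude envelope, and forms the quadrature (cosine) component from the
#' analytic signal, so the cosine leads the sine by a quarter cycle at the
#' carrier.  Tracks slow frequency/phase wander of the mains.
#'
#' @param noise_ref numeric signal sampled at `fs` containing the mains
#'   interference (a dedicated noise channel, or an EEG average).
#' @param fs sampling rate, Hz.
#' @param f0 mains frequency, Hz (50 in Europe, 60 elsewhere).
#' @param bw band-pass full width around `f0`, Hz.
#' @return list with unit-amplitude `sine` and `cosine` signals and the
#'   band `envelope` (muV).
#' @export
extract_fundamental <- function(noise_ref, fs, f0 = 50, bw = 2) {
  stopifnot(f0 - bw / 2 > 0, f0 + bw / 2 < fs / 2)
  total_rms <- sqrt(mean(noise_ref^2))
  if (total_rms == 0) stop("no mains component detected: reference is flat")
  band <- fir_zero_phase(noise_ref, fir_bandpass_taps(fs, f0 - bw / 2, f0 + bw / 2))
  band_pow <- mean(band^2)
  if (band_pow < 1e-24 || band_pow / total_rms^2 < 1e-2)
    stop("no mains component detected: in-band energy below floor")
  z <- analytic_signal(band)
  env <- Mod(z)
  if (any(env < 1e-12)) stop("mains envelope vanishes; cannot normalise")
  # band = sin(theta) convention: analytic signal of sin is sin - i cos
  list(sine = band / env, cosine = -Im(z) / env, envelope = env)
}

#' Build harmonic regressors from a fundamental quadrature pair
#'
#' Applies the angle-addition recursion to generate `sin(k theta)` and
#' `cos(k theta)` for `k = 1..K` from the instantaneous phase of the
#' fundamental, without ever estimating the phase explicitly.
#'
#' @param sine,cosine unit-amplitude fundamental pair from
#'   [extract_fundamental()].
#' @param K number of harmonics (including the fundamental), >= 1.
#' @param f0,fs optional; if both given, `K * f0 < fs / 2` is enforced.
#' @return numeric matrix with `2K` columns named `sin1, cos1, sin2, ...`.
#' @export
build_harmonics <- function(sine, cosine, K, f0 = NULL, fs = NULL) {
  stopifnot(K >= 1, length(sine) == length(cosine))
  if (!is.null(f0) && !is.null(fs) && K * f0 >= fs / 2)
    stop("K * f0 = ", K * f0, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  out <- matrix(0, nrow = length(sine), ncol = 2L * K)
  colnames(out) <- paste0(rep(c("sin", "cos"), K), rep(seq_len(K), each = 2L))
  s <- sine; c_ <- cosine
  out[, 1L] <- s; out[, 2L] <- c_
  if (K > 1L) for (k in 2:K) {
    s_next <- s * cosine + c_ * sine
    c_next <- c_ * cosine - s * sine
    out[, 2L * k - 1L] <- s_next
    out[, 2L * k] <- c_next
    s <- s_next; c_ <- c_next
  }
  out
}

#' Cancel mains interference by harmonic regression
#'
#' Fits each channel by ordinary least squares on the harmonic basis (plus
#' an intercept) and subtracts the fitted mains part.  With `block_s` set,
#' weights are re-fitted on consecutive blocks to follow non-stationary
#' interference.
#'
#' @param rec an [recording()].
#' @param noise_ref label of a dedicated mains noise channel, or `NULL` to
#'   fall back to the average of all channels.
#' @param f0 mains frequency, Hz.
#' @param K number of harmonics; default all below `0.9 * fs / 2`, capped
#'   at 8.
#' @param bw band-pass width for the fundamental, Hz.
#' @param exclude channel labels left untouched (e.g. the noise channel
#'   itself); the noise reference channel is always excluded.
#' @param block_s optional block length in seconds for piecewise fitting.
#' @return list with the corrected `recording` and the fitted `weights`
#'   matrix (channels x regressors) for audit.
#' @export
cancel_powerline <- function(rec, noise_ref = NULL, f0 = 50, K = NULL, bw = 2,
                             exclude = character(), block_s = NULL) {
  fs <- rec$fs
  if (is.null(K)) K <- max(1L, min(8L, floor(0.9 * (fs / 2) / f0)))
  ref_sig <- if (is.null(noise_ref)) colMeans(rec$samples) else get_channel(rec, noise_ref)
  fund <- extract_fundamental(ref_sig, fs, f0 = f0, bw = bw)
  basis <- build_harmonics(fund$sine, fund$cosine, K, f0 = f0, fs = fs)
  BtB <- crossprod(basis)
  if (rcond(BtB) < 1e-10 || qr(BtB)$rank < ncol(basis))
    stop("rank-deficient mains basis")
  skip <- union(exclude, noise_ref)
  targets <- setdiff(rec$channel_labels, skip)
  n <- ncol(rec$samples)
  blocks <- if (is.null(block_s)) list(seq_len(n)) else {
    bl <- max(1L, round(block_s * fs))
    split(seq_len(n), ceiling(seq_len(n) / bl))
  }
  weights <- matrix(NA_real_, nrow = length(rec$channel_labels), ncol = ncol(basis),
                    dimnames = list(rec$channel_labels, colnames(basis)))
  out <- rec
  # per-block normal equations, shared across channels
  XtX <- lapply(blocks, function(idx) {
    Xb <- cbind(1, basis[idx, , drop = FALSE])
    crossprod(Xb)
  })
  for (lab in targets) {
    x <- get_channel(rec, lab)
    for (bi in seq_along(blocks)) {
      idx <- blocks[[bi]]
      Xb <- cbind(1, basis[idx, , drop = FALSE])
      co <- drop(solve(XtX[[bi]], crossprod(Xb, x[idx])))
      w <- co[-1L]
      x[idx] <- x[idx] - basis[idx, , drop = FALSE] %*% w
      weights[lab, ] <- w   # last block's weights kept for audit
    }
    out <- set_channel(out, lab, x)
  }
  list(recording = out, weights = weights, f0 = f0, K = K)
}
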