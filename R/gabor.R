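# Core EMG spike reduction.  Scalp/neck muscle spikes show a sharp
# potential change over ~3.5 ms and are well modelled by Gabor atoms — a
# sinusoid under a Gaussian envelope, with the spike's shape controlled by
# the phase of the sinusoid relative to the envelope centre.  The stages
# are: (1) detect sharp 3.5 ms potential changes on a 10 Hz high-passed
# copy; (2) locate the envelope centre where the first and third discrete
# differentials are most negatively correlated; (3) estimate the envelope
# spread from the gradient ratio at the centre vs 1 ms earlier; (4) refine
# the centre time in 0.01 ms steps; (5) fit amplitude and phase by
# quadrature regression and subtract the fitted atom from the *unfiltered*
# signal.  Atoms are processed in temporal order, each subtraction applied
# before later candidates are evaluated (sequential greedy).

#' Evaluate a Gabor atom
#'
#' `g(t) = A * sin(2 pi f (t - t0) + phi) * exp(-(t - t0)^2 / (2 sigma^2))`.
#'
#' @param time_grid times at which to evaluate, seconds (uniform at the
#'   sampling rate).
#' @param t0 Gaussian centre, s.
#' @param sigma Gaussian spread, s (> 0).
#' @param f carrier frequency, Hz.
#' @param phi phase of the sinusoid at the Gaussian centre, rad.
#' @param A amplitude, muV.
#' @return numeric vector of atom values.
#' @export
gabor_waveform <- function(time_grid, t0, sigma, f, phi = 0, A = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  dt <- time_grid - t0
  A * sin(2 * pi * f * dt + phi) * exp(-dt^2 / (2 * sigma^2))
}

#' Detection configuration for EMG spike reduction
#'
#' Defaults follow the standard settings: a 7 muV minimum potential change
#' over 3.5 ms (optimisable in 4-9 muV), a first/third-differential
#' correlation gate of -0.78 at 2 kHz sampling and -0.84 at 5 kHz, a 5 ms
#' centre-search half-window, and a 10 Hz zero-phase FIR detection
#' pre-filter.  The carrier frequency defaults to `1 / (2 * delta_t)`
#' (~142.9 Hz) so one half-cycle of the sinusoid spans the 3.5 ms
#' signature; at sampling rates >= 5 kHz an extra quadrature pair at twice
#' the carrier captures higher-frequency spike components.
#'
#' @param fs sampling rate, Hz.
#' @param delta_t sharp-change span, s.
#' @param v_thresh minimum potential change over `delta_t`, muV.
#' @param corr_thresh most positive allowed d1-d3 correlation at the
#'   accepted centre; candidates with a weaker (less negative) correlation
#'   are rejected.
#' @param search_ms centre-search half-window, ms.
#' @param hp_cutoff detection pre-filter cutoff, Hz.
#' @param f carrier frequency of the fitted atoms, Hz.
#' @param sigma_grid_ms spread-lookup grid, ms.
#' @param refine_step_s centre refinement step, s.
#' @param max_steps refinement step cap (bounds the search to ~2 ms).
#' @param extra_hf include a second quadrature pair at `2 f` in the fit.
#' @return a `detection_config` list.
#' @export
detection_config <- function(fs,
                             delta_t = 0.0035,
                             v_thresh = 7,
                             corr_thresh = if (fs >= 3500) -0.84 else -0.78,
                             search_ms = 5,
                             hp_cutoff = 10,
                             f = 1 / (2 * delta_t),
                             sigma_grid_ms = seq(0.5, 6, by = 0.05),
                             refine_step_s = 1e-5,
                             max_steps = 200L,
                             extra_hf = fs >= 5000) {
  stopifnot(v_thresh > 0, corr_thresh > -1, corr_thresh < 0,
            round(delta_t * fs) >= 2, f < fs / 2)
  structure(list(fs = fs, delta_t = delta_t, v_thresh = v_thresh,
                 corr_thresh = corr_thresh, search_ms = search_ms,
                 hp_cutoff = hp_cutoff, f = f,
                 sigma_grid_ms = sigma_grid_ms,
                 refine_step_s = refine_step_s, max_steps = max_steps,
                 w_corr = round(delta_t * fs), extra_hf = extra_hf),
            class = "detection_config")
}

#' Detect sharp-potential-change spike candidates
#'
#' Candidates are local maxima of `|x(i + n_d) - x(i)|` (with
#' `n_d = round(delta_t * fs)`) strictly exceeding `v_thresh`, each
#' reported at the index of the steepest single-sample gradient within the
#' span.  Candidates closer than `n_d` samples are merged, keeping the
#' larger change.  `x` should already be high-pass filtered at
#' `cfg$hp_cutoff` (the detection copy); later fitting uses the unfiltered
#' signal.
#'
#' @param x detection signal (high-passed), muV.
#' @param fs sampling rate, Hz.
#' @param cfg a [detection_config()].
#' @return integer vector of candidate sample indices (1-based).
#' @export
detect_candidates <- function(x, fs, cfg = detection_config(fs)) {
  nd <- round(cfg$delta_t * fs)
  n <- length(x)
  if (n < 2L * nd) stop("signal shorter than twice the sharp-change span")
  d <- x[(nd + 1L):n] - x[seq_len(n - nd)]
  score <- abs(d)
  m <- length(score)
  is_max <- score > cfg$v_thresh
  is_max[2:m] <- is_max[2:m] & score[2:m] > score[1:(m - 1L)]
  is_max[1:(m - 1L)] <- is_max[1:(m - 1L)] & score[1:(m - 1L)] >= score[2:m]
  peaks <- which(is_max)
  if (!length(peaks)) return(integer(0))
  g <- abs(diff(x))
  cand <- integer(0); val <- numeric(0)
  for (i in peaks) {
    j <- i - 1L + which.max(g[i:min(i + nd - 1L, n - 1L)])
    if (length(cand) && j - cand[length(cand)] < nd) {
      if (score[i] > val[length(val)]) {       # merge: keep larger change
        cand[length(cand)] <- j
        val[length(val)] <- score[i]
      }
    } else {
      cand <- c(cand, j)
      val <- c(val, score[i])
    }
  }
  cand
}

#' Locate the Gaussian centre via the d1/d3 correlation gate
#'
#' Near the envelope centre a Gabor atom approximates a sinusoid, and the
#' first and third discrete differentials of a sinusoid are inversely
#' proportional; the centre is therefore taken as the point, within
#' `search_ms` of the candidate, where the sliding-window correlation of
#' d1 and d3 is most negative.  Candidates whose best correlation is
#' weaker (more positive) than `cfg$corr_thresh` are rejected.
#'
#' @param x signal, muV.
#' @param fs sampling rate, Hz.
#' @param candidate_idx candidate sample index from [detect_candidates()].
#' @param cfg a [detection_config()].
#' @return `list(center, corr)` or `NULL` when rejected.
#' @export
locate_center <- function(x, fs, candidate_idx, cfg = detection_config(fs)) {
  n <- length(x)
  h <- max(2L, floor(cfg$w_corr / 2))
  m <- round(cfg$search_ms * fs / 1000)
  # work on a local slice: everything the search can touch
  lo <- max(1L, candidate_idx - m - h - 4L)
  hi <- min(n, candidate_idx + m + h + 4L)
  x <- x[lo:hi]
  n <- length(x)
  candidate_idx <- candidate_idx - lo + 1L
  # d1[k] and d3[k] are paired at equal start index k, i.e. deliberately
  # offset by one sample in centre time.  At the carrier scale (~143 Hz,
  # heavily oversampled) this offset is a negligible phase error and the
  # pair stays near -1 at a spike centre; for broadband noise, whose
  # energy sits near Nyquist after differencing, the offset flips the
  # intrinsic d1/d3 anticorrelation to a positive value, so noise fails
  # the negative-correlation gate.  (This also explains the laxer gate at
  # coarser sampling: the one-sample phase error grows with 1/fs.)
  d1 <- diff(x); d3 <- diff(x, differences = 3L)
  a <- d1[seq_len(n - 3L)]; b <- d3
  np <- length(b)
  j_lo <- max(candidate_idx - m, h + 1L)
  j_hi <- min(candidate_idx + m, np - h)
  if (j_lo > j_hi) return(NULL)
  # window at centre j covers pairs (j - h):(j + h - 1), length 2h
  ca <- cumsum(c(0, a)); cb <- cumsum(c(0, b))
  caa <- cumsum(c(0, a^2)); cbb <- cumsum(c(0, b^2)); cab <- cumsum(c(0, a * b))
  js <- j_lo:j_hi
  k0 <- js - h; k1 <- js + h - 1L
  ok <- k0 >= 1L & k1 <= np
  js <- js[ok]; k0 <- k0[ok]; k1 <- k1[ok]
  if (!length(js)) return(NULL)
  nw <- k1 - k0 + 1L
  sa <- ca[k1 + 1L] - ca[k0]; sb <- cb[k1 + 1L] - cb[k0]
  saa <- caa[k1 + 1L] - caa[k0]; sbb <- cbb[k1 + 1L] - cbb[k0]
  sab <- cab[k1 + 1L] - cab[k0]
  va <- saa - sa^2 / nw; vb <- sbb - sb^2 / nw
  denom <- sqrt(pmax(va * vb, 0))
  r <- ifelse(denom > 0, (sab - sa * sb / nw) / denom, 0)
  best <- which.min(r)
  if (r[best] > cfg$corr_thresh) return(NULL)
  # for odd-phase atoms the most sinusoid-like point sits up to ~1 ms off
  # the envelope centre (the centre itself is envelope-dominated); this is
  # only the first guess, refined to 0.01 ms later
  list(center = js[best] + lo - 1L, corr = r[best])
}

# sigma lookup: expected ratio of the gradient at the atom centre to the
# gradient 1 ms earlier, from the closed form of the atom derivative
#   g'(t) = [w cos(w t) - (t/s^2) sin(w t)] exp(-t^2 / 2 s^2),  w = 2 pi f.
# r(sigma) = g'(0)/g'(-1 ms) has a pole where the envelope and carrier
# terms cancel (~1.2 ms at the default carrier): above the pole the ratio
# decreases monotonically from +Inf towards ~1.7 (the invertible branch);
# below it the ratio is negative and non-monotone, so such measurements
# are resolved by a grid search instead.
.sigma_tables <- new.env(parent = emptyenv())

sigma_ratio_table <- function(fs, f, sigma_grid_ms) {
  key <- paste(f, length(sigma_grid_ms), sigma_grid_ms[1L],
               sigma_grid_ms[length(sigma_grid_ms)], sep = "|")
  if (!is.null(.sigma_tables[[key]])) return(.sigma_tables[[key]])
  tau <- 1e-3
  w <- 2 * pi * f
  sg <- sigma_grid_ms / 1000
  denom <- (w * cos(w * tau) - (tau / sg^2) * sin(w * tau)) *
    exp(-tau^2 / (2 * sg^2))
  ratios <- w / denom
  neg <- which(ratios <= 0)
  branch_start <- if (length(neg)) max(neg) + 1L else 1L
  tab <- list(sigma_ms = sigma_grid_ms, ratio = ratios,
              branch_start = branch_start)
  .sigma_tables[[key]] <- tab
  tab
}

#' Estimate the Gaussian spread of a spike
#'
#' The ratio of the discrete gradient at the centre to the gradient 1 ms
#' earlier is matched against a precomputed table of expected ratios over a
#' spread grid (default 0.5-6 ms in 0.05 ms steps) and inverted by
#' interpolation on the table's monotone branch, clamping at the grid ends
#' with a warning.  When `refine = TRUE` (the default, used by
#' [reduce_emg()]) the table estimate seeds a local grid search maximising
#' the fraction of windowed signal energy captured by the quadrature atom
#' pair, which is robust to the spike's unknown phase.  A vanishing
#' reference gradient falls back to the full grid search.
#'
#' @param x signal, muV.
#' @param fs sampling rate, Hz.
#' @param center_idx located centre sample index.
#' @param cfg a [detection_config()].
#' @param refine run the local projection-based grid refinement.
#' @return estimated sigma, seconds.
#' @export
estimate_sigma <- function(x, fs, center_idx, cfg = detection_config(fs),
                           refine = TRUE) {
  n1 <- max(1L, round(0.001 * fs))
  n <- length(x)
  grid <- cfg$sigma_grid_ms
  tab <- sigma_ratio_table(fs, cfg$f, grid)
  grad <- function(i) (x[i + 1L] - x[i - 1L]) / 2
  sig_ms <- NA_real_
  ambiguous <- FALSE
  if (center_idx - n1 - 1L >= 1L && center_idx + 1L <= n) {
    g0 <- grad(center_idx); g1 <- grad(center_idx - n1)
    if (is.finite(g0) && is.finite(g1) && abs(g1) > 1e-9 * max(abs(g0), 1e-12)) {
      r <- g0 / g1
      br <- tab$branch_start:length(grid)
      rb <- tab$ratio[br]; sb <- grid[br]   # rb strictly decreasing
      if (!is.finite(r)) {
        # leave NA -> grid search
      } else if (r <= 0) {
        # below the pole: non-invertible small-sigma territory
        sig_ms <- grid[1L]
        warning("gradient ratio below the invertible branch; sigma clamped to grid minimum")
        ambiguous <- TRUE
      } else if (r >= rb[1L]) {
        sig_ms <- sb[1L]                    # just above the pole
        ambiguous <- TRUE
      } else if (r <= rb[length(rb)]) {
        sig_ms <- sb[length(sb)]
        warning("gradient ratio beyond the table; sigma clamped to grid maximum")
        ambiguous <- r < rb[length(rb)] - 0.05
      } else {
        sig_ms <- stats::approx(rev(rb), rev(sb), xout = r, ties = "ordered")$y
      }
    }
  }
  full_search <- is.na(sig_ms) || (refine && ambiguous)
  if (is.na(sig_ms)) message("degenerate gradient at centre; sigma by full grid search")
  if (refine || full_search) {
    t0 <- (center_idx - 1L) / fs
    cand <- if (full_search) {
      grid[seq.int(1L, length(grid), by = 5L)]   # coarse; polished later
    } else {
      i0 <- which.min(abs(grid - sig_ms))
      grid[max(1L, i0 - 10L):min(length(grid), i0 + 10L)]
    }
    en <- vapply(cand, function(sm)
      .gabor_quad_energy(x, fs, t0, sm / 1000, cfg$f), 0)
    sig_ms <- cand[which.max(en)]
  }
  sig_ms / 1000
}

# Quadrature projection of the signal onto {sin, cos} Gabor atoms (plus an
# optional pair at 2f) over the support window t0 +/- 4 sigma.  Returns the
# captured energy fraction r2, the captured energy itself (the
# matching-pursuit objective used for localisation), the coefficients,
# and the window indices.
quad_fit <- function(x, fs, t0, sigma, f, extra_hf = FALSE) {
  n <- length(x)
  i0 <- max(1L, floor((t0 - 4 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((t0 + 4 * sigma) * fs) + 1L)
  if (i1 - i0 + 1L < 4L) return(list(r2 = 0, energy = 0, ok = FALSE))
  idx <- i0:i1
  tg <- (idx - 1L) / fs - t0
  G <- exp(-tg^2 / (2 * sigma^2))
  w <- 2 * pi * f * tg
  s <- sin(w) * G
  c_ <- cos(w) * G
  y <- x[idx]
  # direct normal equations (2 or 4 unknowns); the basis is far from
  # collinear except for sigma << 1/f, which the rcond guard catches
  if (extra_hf) {
    s2 <- sin(2 * w) * G
    c2 <- cos(2 * w) * G
    X <- cbind(s, c_, s2, c2)
  } else {
    X <- cbind(s, c_)
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- tryCatch(drop(solve(XtX, Xty)), error = function(e) NULL)
  if (is.null(beta) || rcond(XtX) < 1e-10)
    return(list(r2 = 0, energy = 0, ok = FALSE))
  energy <- sum(beta * Xty)            # == ||projection||^2
  ss <- sum(y^2)
  r2 <- if (ss > 0) energy / ss else 0
  if (!is.finite(r2)) r2 <- 0
  if (!is.finite(energy)) energy <- 0
  list(r2 = r2, energy = energy, beta = beta, idx = idx, ok = TRUE)
}

# Alternate sub-sample t0 refinement with local sigma grid search until
# neither parameter moves (the quadrature fit makes phase implicit, so the
# energy-fraction objective is a function of t0 and sigma only).  This is
# the polish applied between location and amplitude fitting.
polish_spike <- function(x, fs, spike, cfg, cycles = 3L) {
  grid <- cfg$sigma_grid_ms
  out <- .polish_spike_cpp(x, fs, spike$t0, spike$sigma, spike$f %||% cfg$f,
                           cfg$refine_step_s, cfg$max_steps,
                           grid[1L] / 1000, grid[length(grid)] / 1000,
                           cycles)
  spike$t0 <- out[1L]
  spike$sigma <- out[2L]
  spike$corr <- out[3L]
  spike
}

#' Refine a spike's centre time by sub-sample hill climbing
#'
#' Shifts `t0` in `cfg$refine_step_s` increments (default 0.01 ms),
#' regenerating the atom on the sample grid at each shift, and keeps
#' shifting while the Gabor-EEG correlation (energy fraction captured by
#' the quadrature pair) increases; stops when neither direction improves or
#' after `cfg$max_steps` steps.
#'
#' @param x signal, muV.
#' @param fs sampling rate, Hz.
#' @param spike list with at least `t0` (s) and `sigma` (s).
#' @param cfg a [detection_config()].
#' @return the spike with updated `t0` and `corr` (sqrt of captured energy
#'   fraction).
#' @export
refine_center <- function(x, fs, spike, cfg = detection_config(fs)) {
  step <- cfg$refine_step_s
  f <- spike$f %||% cfg$f
  # localisation always scores against the base quadrature pair (the 2f
  # pair is only added in the final amplitude fit) and maximises the
  # captured energy, the matching-pursuit objective: noise contributes a
  # roughly position-independent two-degree-of-freedom share, while the
  # atom's energy peaks sharply at its true centre
  score <- function(t0) quad_fit(x, fs, t0, spike$sigma, f, extra_hf = FALSE)$energy
  t0 <- spike$t0
  cur <- score(t0)
  for (dir in c(1, -1)) {
    moved <- FALSE
    for (k in seq_len(cfg$max_steps)) {
      nxt <- score(t0 + dir * step)
      if (nxt > cur) {
        t0 <- t0 + dir * step
        cur <- nxt
        moved <- TRUE
      } else break
    }
    if (moved) break   # improvement found in this direction; done
  }
  spike$t0 <- t0
  spike$corr <- sqrt(max(quad_fit(x, fs, t0, spike$sigma, f, extra_hf = FALSE)$r2, 0))
  spike
}

# Canonical atom evaluation over its support window; both the subtraction
# and the inventory reconstruction use this exact expression so that
# corrected = input - sum(atoms) holds bit-exactly.
atom_window <- function(n, fs, t0, sigma, f, phi, A, A2 = 0, phi2 = 0) {
  i0 <- max(1L, floor((t0 - 4 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((t0 + 4 * sigma) * fs) + 1L)
  idx <- i0:i1
  tg <- (idx - 1L) / fs - t0
  G <- exp(-tg^2 / (2 * sigma^2))
  v <- A * sin(2 * pi * f * tg + phi) * G
  if (A2 != 0) v <- v + A2 * sin(2 * pi * (2 * f) * tg + phi2) * G
  list(idx = idx, values = v)
}

#' Fit a spike's amplitude and phase and subtract the atom
#'
#' Ordinary least squares of the signal on a sin/cos quadrature pair at the
#' carrier frequency over the support window `t0 +/- 4 sigma` (the two
#' coefficients capture amplitude and phase jointly), plus a second
#' quadrature pair at twice the carrier when `extra_hf`.  The fitted
#' waveform is subtracted; samples outside the support window are
#' untouched.
#'
#' @param x unfiltered signal, muV.
#' @param fs sampling rate, Hz.
#' @param spike list with `t0` (s), `sigma` (s) and optionally `f` (Hz).
#' @param cfg a [detection_config()].
#' @param extra_hf include the pair at `2 f`; defaults to `cfg$extra_hf`.
#' @return `list(signal, spike)` — the corrected signal and the spike
#'   completed with `A` (muV), `phi`, `A2`, `phi2`, `corr`; `NULL` if the
#'   design is singular (e.g. sigma much smaller than a carrier cycle).
#' @export
fit_amplitude_and_subtract <- function(x, fs, spike, cfg = detection_config(fs),
                                       extra_hf = cfg$extra_hf) {
  n <- length(x)
  if (floor((spike$t0 - 4 * spike$sigma) * fs) + 1L < 1L ||
      ceiling((spike$t0 + 4 * spike$sigma) * fs) + 1L > n)
    stop("support window t0 +/- 4 sigma extends outside the signal")
  f <- spike$f %||% cfg$f
  qf <- quad_fit(x, fs, spike$t0, spike$sigma, f, extra_hf)
  if (!qf$ok) return(NULL)
  b <- unname(qf$beta)
  spike$f <- f
  spike$A <- sqrt(b[1L]^2 + b[2L]^2)
  spike$phi <- atan2(b[2L], b[1L])
  if (extra_hf) {
    spike$A2 <- sqrt(b[3L]^2 + b[4L]^2)
    spike$phi2 <- atan2(b[4L], b[3L])
  } else {
    spike$A2 <- 0
    spike$phi2 <- 0
  }
  aw <- atom_window(n, fs, spike$t0, spike$sigma, f, spike$phi, spike$A,
                    spike$A2, spike$phi2)
  y <- x[aw$idx]
  ss <- sum(y^2)
  spike$corr <- if (ss > 0) sum(aw$values * y) / sqrt(ss * sum(aw$values^2)) else 0
  x[aw$idx] <- x[aw$idx] - aw$values
  list(signal = x, spike = spike)
}

#' Detect, fit and subtract all muscle spikes in a recording
#'
#' Runs the full per-channel chain: 10 Hz high-pass detection copy, sharp
#' 3.5 ms change detection, d1/d3 centre location with the correlation
#' gate, gradient-ratio spread estimation, 0.01 ms centre refinement, and
#' quadrature amplitude fitting with subtraction from the unfiltered
#' signal.  Candidates are processed in temporal order and each fitted atom
#' is removed before later candidates are evaluated, so overlapping spikes
#' are fitted on the residual.  Per-candidate failures are skipped.
#' Power-line and SMP corrections should already have been applied.
#'
#' @param rec an [recording()].
#' @param cfg a [detection_config()] (defaults for `rec$fs`).
#' @param channels channels to process (default: all).
#' @return list with the corrected `recording` and `spikes`, a data frame
#'   inventory (channel, t0_s, sigma_ms, f_hz, phi_rad, amp_uv, amp2_uv,
#'   phi2_rad, corr) that fully explains the modification:
#'   corrected = input - sum of the inventory's atoms, exactly.
#' @export
reduce_emg <- function(rec, cfg = detection_config(rec$fs),
                       channels = rec$channel_labels) {
  fs <- rec$fs
  tab <- sigma_ratio_table(fs, cfg$f, cfg$sigma_grid_ms)
  search_n <- round(cfg$search_ms * fs / 1000)
  out <- rec
  invs <- list()
  for (lab in channels) {
    x <- get_channel(rec, lab)
    xhp <- highpass_zero_phase(x, fs, cfg$hp_cutoff)
    cands <- detect_candidates(xhp, fs, cfg)
    res <- .reduce_channel_cpp(x, fs, as.integer(cands), cfg$corr_thresh,
                               search_n, cfg$w_corr, cfg$f,
                               cfg$sigma_grid_ms, tab$ratio, tab$branch_start,
                               cfg$refine_step_s, cfg$max_steps,
                               cfg$extra_hf)
    m <- res$inventory
    if (nrow(m)) {
      invs[[lab]] <- data.frame(channel = lab, t0_s = m[, 1L],
                                sigma_ms = m[, 2L], f_hz = m[, 3L],
                                phi_rad = m[, 4L], amp_uv = m[, 5L],
                                amp2_uv = m[, 6L], phi2_rad = m[, 7L],
                                corr = m[, 8L])
    }
    out <- set_channel(out, lab, res$x)
  }
  spikes <- if (length(invs)) do.call(rbind, c(invs, make.row.names = FALSE)) else
    data.frame(channel = character(), t0_s = numeric(), sigma_ms = numeric(),
               f_hz = numeric(), phi_rad = numeric(), amp_uv = numeric(),
               amp2_uv = numeric(), phi2_rad = numeric(), corr = numeric())
  list(recording = out, spikes = spikes)
}

#' Reconstruct the summed atom waveform described by a spike inventory
#'
#' Re-evaluates every inventory atom with the same canonical expression
#' used at subtraction time, so `input - spikes_waveform(...)` reproduces
#' the corrected signal exactly.
#'
#' @param spikes inventory data frame from [reduce_emg()] (or a truth table
#'   from [simulate_eeg()], which shares the schema).
#' @param n signal length, samples.
#' @param fs sampling rate, Hz.
#' @param channel channel label to reconstruct.
#' @return numeric vector of length `n`.
#' @export
spikes_waveform <- function(spikes, n, fs, channel) {
  v <- numeric(n)
  rows <- spikes[spikes$channel == channel, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    aw <- atom_window(n, fs, rows$t0_s[i], rows$sigma_ms[i] / 1000,
                      rows$f_hz[i], rows$phi_rad[i], rows$amp_uv[i],
                      rows$amp2_uv[i] %||% 0, rows$phi2_rad[i] %||% 0)
    v[aw$idx] <- v[aw$idx] + aw$values
  }
  v
}
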