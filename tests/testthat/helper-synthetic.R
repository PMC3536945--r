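# Shared fixtures built in code.

# short multichannel recording of band-limited background noise
toy_recording <- function(fs = 2000, dur = 2, labels = c("C3", "CZ"),
                          rms = 3, seed = 1) {
  set.seed(seed)
  n <- fs * dur
  samples <- t(vapply(labels, function(l) gaborclean:::pink_noise(n, fs, rms, 1),
                      numeric(n)))
  recording(samples, fs = fs, channel_labels = labels)
}

# exhaustive grid-search least-squares oracle for a single Gabor atom:
# for every (t0, sigma) on the grids, fit the quadrature amplitudes by
# closed-form 2x2 normal equations and keep the fit with the largest
# captured energy (equivalently, smallest residual sum of squares).
# Plain R, independent of the package's localisation path.
oracle_gabor_fit <- function(x, fs, f, t0_grid, sigma_grid_s) {
  n <- length(x)
  best <- list(energy = -Inf)
  for (sg in sigma_grid_s) {
    for (tc in t0_grid) {
      i0 <- max(1L, floor((tc - 4 * sg) * fs) + 1L)
      i1 <- min(n, ceiling((tc + 4 * sg) * fs) + 1L)
      idx <- i0:i1
      tg <- (idx - 1L) / fs - tc
      G <- exp(-tg^2 / (2 * sg^2))
      s <- sin(2 * pi * f * tg) * G
      c_ <- cos(2 * pi * f * tg) * G
      y <- x[idx]
      ss <- sum(s * s); cc <- sum(c_ * c_); sc <- sum(s * c_)
      sy <- sum(s * y); cy <- sum(c_ * y)
      det <- ss * cc - sc * sc
      if (det <= 0) next
      b1 <- (cc * sy - sc * cy) / det
      b2 <- (ss * cy - sc * sy) / det
      energy <- b1 * sy + b2 * cy
      if (energy > best$energy) {
        best <- list(energy = energy, t0 = tc, sigma = sg,
                     A = sqrt(b1^2 + b2^2), phi = atan2(b2, b1))
      }
    }
  }
  best
}

# spike-free cohort-style spec for fast tests
quiet_spec <- function(..., seed = 1) {
  args <- list(channels = c("C3", "CZ"), n_events = 10L,
               mains_amp_uv = 0, include_mains_channel = FALSE,
               smp_rate_hz = 0, include_smp_refs = FALSE, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_spec, args)
}
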