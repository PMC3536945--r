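# Event-related synchronisation (ERS) statistics for the 65-85 Hz motor
# gamma.  Per trial, the "peak" amplitude (mean band amplitude over
# 0-250 ms after the button press) is compared with the baseline (up to 1 s
# before the press, shortened to start 250 ms after the previous press when
# presses are close).  Tests are paired t tests: one-tailed for the
# presence of the ERS (peak > baseline) and for amplitude reductions with
# artifact correction, two-tailed for the effect of correction on the
# baseline-corrected peak (direction not predicted).

#' Baseline window for one trial
#'
#' Default `[t - 1, t]` seconds before the press at `t`; if the previous
#' press is closer than 1.25 s, the window starts 250 ms after it (so it
#' never overlaps the previous trial's 0-250 ms peak window).  Returns
#' `NULL` (trial excluded) if the previous press is 0.25 s or less before
#' the current one.
#'
#' @param event_times sorted press times, seconds.
#' @param trial_index which press.
#' @param baseline_s full baseline length, seconds.
#' @param guard_s dead time after the previous press, seconds.
#' @return `c(start, end)` in seconds, or `NULL`.
#' @export
baseline_window <- function(event_times, trial_index, baseline_s = 1,
                            guard_s = 0.25) {
  t <- event_times[trial_index]
  lo <- t - baseline_s
  if (trial_index > 1L) {
    prev <- event_times[trial_index - 1L]
    if (t - prev <= guard_s) return(NULL)
    if (t - prev < baseline_s + guard_s) lo <- prev + guard_s
  }
  c(lo, t)
}

# Paired one/two-tailed t test computed in closed form (d = x - y).
# one-tailed alternative: mean(d) > 0.
paired_t <- function(x, y, tail = c("one", "two")) {
  tail <- match.arg(tail)
  d <- x - y
  n <- length(d)
  stopifnot(n >= 2L)
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    t_ <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) ifelse(tail == "one", 0.5, 1) else
      if (tail == "one") ifelse(m > 0, 0, 1) else 0
  } else {
    t_ <- m / (s / sqrt(n))
    p <- if (tail == "one") stats::pt(t_, n - 1L, lower.tail = FALSE) else
      2 * stats::pt(abs(t_), n - 1L, lower.tail = FALSE)
  }
  list(t = t_, p = p, df = n - 1L, mean_diff = m, tail = tail,
       degenerate = degenerate)
}

#' Test for an event-related synchronisation
#'
#' Paired one-tailed t test of peak vs baseline amplitude over the kept
#' trials (within-subject) — or, given per-subject means, over subjects
#' (across-subject; pass `mask = NULL`).
#'
#' @param peak per-trial (or per-subject) peak-window band amplitude.
#' @param baseline matching baseline band amplitude.
#' @param mask optional `epoch_mask` restricting to kept trials.
#' @param tail `"one"` (peak > baseline; default) or `"two"`.
#' @return an `ers_result`: per-trial values used, means, `t`, `p`, `df`.
#' @export
ers_test <- function(peak, baseline, mask = NULL, tail = "one") {
  stopifnot(length(peak) == length(baseline))
  if (!is.null(mask)) {
    stopifnot(length(mask$keep) == length(peak))
    peak <- peak[mask$keep]
    baseline <- baseline[mask$keep]
  }
  ok <- is.finite(peak) & is.finite(baseline)
  peak <- peak[ok]; baseline <- baseline[ok]
  if (length(peak) < 2L) stop("need at least 2 usable trials/subjects for the ERS test")
  tt <- paired_t(peak, baseline, tail)
  structure(list(peak = peak, baseline = baseline,
                 mean_peak = mean(peak), mean_baseline = mean(baseline),
                 mean_ers = mean(peak - baseline),
                 t = tt$t, p = tt$p, df = tt$df, tail = tt$tail,
                 degenerate = tt$degenerate, n = length(peak)),
            class = "ers_result")
}

#' @export
print.ers_result <- function(x, ...) {
  cat(sprintf("<ers_result> n=%d  mean peak %.4g, baseline %.4g (ERS %.4g)  t(%d)=%.3f, %s-tailed p=%.4g\n",
              x$n, x$mean_peak, x$mean_baseline, x$mean_ers, x$df, x$t, x$tail, x$p))
  invisible(x)
}

#' Effect of an artifact-correction stage
#'
#' Compares a condition before vs after one correction stage on identical
#' trials: a one-tailed paired t test for the *reduction* of pre-press
#' baseline amplitude (correction is expected to remove EMG), and a
#' two-tailed paired t test for the change in the baseline-corrected peak
#' (no predicted direction).
#'
#' @param baseline_pre,baseline_post per-trial (or per-subject) pre-press
#'   band amplitude before/after the correction.
#' @param peak_effect_pre,peak_effect_post optional baseline-corrected peak
#'   magnitudes before/after; if given, the two-tailed peak test is run.
#' @param mask_pre,mask_post `epoch_mask`s of the two conditions; must be
#'   identical (provenance enforced).  `NULL` for subject-level input.
#' @return list with `baseline_test` (one-tailed, reduction) and
#'   `peak_test` (two-tailed) results.
#' @export
correction_effect_test <- function(baseline_pre, baseline_post,
                                   peak_effect_pre = NULL, peak_effect_post = NULL,
                                   mask_pre = NULL, mask_post = NULL) {
  if (!is.null(mask_pre) || !is.null(mask_post)) {
    check_same_mask(mask_pre, mask_post)
    baseline_pre <- baseline_pre[mask_pre$keep]
    baseline_post <- baseline_post[mask_pre$keep]
    if (!is.null(peak_effect_pre)) {
      peak_effect_pre <- peak_effect_pre[mask_pre$keep]
      peak_effect_post <- peak_effect_post[mask_pre$keep]
    }
  }
  out <- list(baseline_test = paired_t(baseline_pre, baseline_post, "one"))
  if (!is.null(peak_effect_pre))
    out$peak_test <- paired_t(peak_effect_post, peak_effect_pre, "two")
  out
}

#' Z-score topography of the ERS
#'
#' Per derivation, `Z = mean(baseline-corrected ERS) / SD` with mean and SD
#' across trials.  Derivations with zero SD get `NA`.
#'
#' @param ers_by_derivation numeric matrix, trials x derivations, of
#'   per-trial baseline-corrected ERS values; column names label the
#'   derivations (e.g. `"C3-CZ"`).
#' @return a `topography_z`: named `z` vector and `n_trials`.
#' @export
topography_z <- function(ers_by_derivation) {
  stopifnot(is.matrix(ers_by_derivation), nrow(ers_by_derivation) >= 2L)
  mu <- colMeans(ers_by_derivation)
  sd_ <- apply(ers_by_derivation, 2L, stats::sd)
  z <- ifelse(sd_ > 0, mu / sd_, NA_real_)
  if (anyNA(z)) message(sum(is.na(z)), " derivation(s) with zero SD: Z undefined")
  names(z) <- colnames(ers_by_derivation)
  structure(list(z = z, n_trials = nrow(ers_by_derivation),
                 n_derivations = ncol(ers_by_derivation)),
            class = "topography_z")
}

#' Average Z topographies across subjects
#' @param maps list of `topography_z` over subjects (same derivations).
#' @return a `topography_z` with the across-subject mean Z.
#' @export
average_topographies <- function(maps) {
  zs <- do.call(rbind, lapply(maps, `[[`, "z"))
  structure(list(z = colMeans(zs, na.rm = TRUE), n_trials = NA_integer_,
                 n_derivations = ncol(zs), n_subjects = length(maps)),
            class = "topography_z")
}

#' Per-trial peak and baseline band amplitudes for a derivation
#'
#' Convenience wrapper: computes the sliding-FFT map of a bipolar
#' derivation, then for every press the mean band amplitude over the peak
#' window (window centres in `t + peak_window`) and over the trial's
#' [baseline_window()].  Trials without a valid baseline get `NA`.
#'
#' @param rec an [recording()].
#' @param events an [event_series()] of button presses.
#' @param anode,cathode derivation channel labels (e.g. "C3", "CZ").
#' @param band `c(f_lo, f_hi)` in Hz (default 65-85).
#' @param peak_window `c(lo, hi)` seconds relative to the press.
#' @param window_samples FFT window length.
#' @return data frame with `peak`, `baseline` and `max_band` (maximum band
#'   amplitude anywhere in the trial span, for the anomaly rule), one row
#'   per press.
#' @export
trial_band_amplitudes <- function(rec, events, anode, cathode,
                                  band = c(65, 85), peak_window = c(0, 0.25),
                                  window_samples = default_window_samples(rec$fs)) {
  x <- derive_bipolar(rec, anode, cathode)
  bs <- stft_band_series(x, rec$fs, window_samples, f_lo = band[1L],
                         f_hi = band[2L], start_time = rec$start_time)
  series <- bs$series
  times <- bs$times
  n_ev <- length(events$times)
  peak <- baseline <- max_band <- rep(NA_real_, n_ev)
  for (i in seq_len(n_ev)) {
    t <- events$times[i]
    peak[i] <- band_window_mean(series, times, t + peak_window[1L],
                                t + peak_window[2L])
    bw <- baseline_window(events$times, i)
    if (!is.null(bw)) baseline[i] <- band_window_mean(series, times, bw[1L], bw[2L])
    sel <- times >= (if (is.null(bw)) t - 1 else bw[1L]) &
      times <= t + peak_window[2L]
    if (any(sel)) max_band[i] <- max(series[sel])
  }
  data.frame(peak = peak, baseline = baseline, max_band = max_band)
}
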