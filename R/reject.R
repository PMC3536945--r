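# Adaptive epoch rejection.  Trials with high 60-130 Hz amplitude (large
# EMG bursts) are rejected against a per-subject threshold
#   threshold = min(a * mean band amplitude over all trials + b, cap)
# with a = 1.5, b = 0.06 muV/Hz, cap 0.4 muV/Hz, never rejecting more than
# 30 of 70 trials.  The mask is decided once, on post-SMP / pre-EMG data,
# and the *same* trials are excluded in every correction condition so that
# between-condition amplitude comparisons are fair.  A final single-pass
# rule drops trials whose peak 65-85 Hz amplitude is more than 6 SD above
# the mean of the kept trials.

#' Rejection configuration
#'
#' @param a threshold multiplier.
#' @param b threshold offset, muV/Hz.
#' @param cap maximum threshold, muV/Hz.
#' @param max_reject_frac largest allowed rejected fraction (30/70).
#' @param sd_limit anomaly rule multiplier.
#' @return a `rejection_config` list.
#' @export
rejection_config <- function(a = 1.5, b = 0.06, cap = 0.4,
                             max_reject_frac = 30 / 70, sd_limit = 6) {
  stopifnot(a > 0, b >= 0, cap > 0, max_reject_frac > 0, max_reject_frac < 1,
            sd_limit > 0)
  structure(list(a = a, b = b, cap = cap, max_reject_frac = max_reject_frac,
                 sd_limit = sd_limit), class = "rejection_config")
}

#' Adaptive rejection threshold
#'
#' `min(a * mean + b, cap)`, then raised just enough if it would reject
#' more than `max_reject_frac` of the trials.
#'
#' @param per_trial_band_amp per-trial mean 60-130 Hz amplitude, muV/Hz.
#' @param cfg a [rejection_config()].
#' @return threshold, muV/Hz.
#' @export
compute_threshold <- function(per_trial_band_amp, cfg = rejection_config()) {
  stopifnot(length(per_trial_band_amp) >= 1L)
  amps <- per_trial_band_amp
  thr <- min(cfg$a * mean(amps) + cfg$b, cfg$cap)
  m <- floor(cfg$max_reject_frac * length(amps))
  if (sum(amps > thr) > m) {
    srt <- sort(amps, decreasing = TRUE)
    thr_new <- srt[m + 1L]   # reject exactly the top m
    message(sprintf("threshold raised %.4g -> %.4g to keep rejections <= %d/%d",
                    thr, thr_new, m, length(amps)))
    thr <- thr_new
  }
  thr
}

#' Build the frozen epoch mask
#'
#' Decided on the post-SMP / pre-EMG condition; trials whose 60-130 Hz
#' amplitude exceeds the adaptive threshold are rejected.  The returned
#' mask carries its provenance and must be reused unchanged for every
#' other condition (enforced by [check_same_mask()]).
#'
#' @param per_trial_band_amp per-trial mean 60-130 Hz amplitude, muV/Hz.
#' @param cfg a [rejection_config()].
#' @param provenance condition the mask was decided on.
#' @return an `epoch_mask`: logical `keep`, `threshold_used`, `reason`
#'   per trial, `provenance`.
#' @export
build_mask <- function(per_trial_band_amp, cfg = rejection_config(),
                       provenance = "post_smp_pre_emg") {
  thr <- compute_threshold(per_trial_band_amp, cfg)
  keep <- per_trial_band_amp <= thr
  stopifnot(any(keep))   # cannot all be rejected after the 30/70 adjustment
  structure(list(keep = keep, threshold_used = thr,
                 reason = ifelse(keep, "", "band_threshold"),
                 provenance = provenance),
            class = "epoch_mask")
}

#' Single-pass 6 SD anomaly rejection
#'
#' Among trials the mask keeps, additionally rejects any whose maximum
#' 65-85 Hz amplitude exceeds mean + `sd_limit` * SD, with mean and SD over
#' the kept trials computed leave-one-out (otherwise a single extreme trial
#' inflates the SD enough to mask itself).  Applied once, without
#' re-estimating after removals.
#'
#' @param per_trial_max_gamma per-trial maximum 65-85 Hz amplitude, muV/Hz.
#' @param mask an `epoch_mask` from [build_mask()].
#' @param cfg a [rejection_config()].
#' @return the updated `epoch_mask`.
#' @export
anomaly_reject <- function(per_trial_max_gamma, mask, cfg = rejection_config()) {
  stopifnot(length(per_trial_max_gamma) == length(mask$keep))
  kept <- which(mask$keep)
  if (length(kept) < 3L) {
    warning("fewer than 3 kept trials; anomaly rule skipped")
    return(mask)
  }
  # leave-one-out mean/SD so a single extreme trial cannot mask itself by
  # inflating the dispersion estimate; still a single pass
  g <- per_trial_max_gamma[kept]
  k <- length(g)
  loo_mean <- (sum(g) - g) / (k - 1)
  loo_sd <- sqrt(pmax(0, ((k - 1) * stats::var(g) - (g - loo_mean)^2 *
                            (k - 1) / k) / (k - 2)))
  bad <- kept[g > loo_mean + cfg$sd_limit * loo_sd]
  mask$keep[bad] <- FALSE
  mask$reason[bad] <- "anomaly_6sd"
  mask
}

#' Enforce cross-condition mask identity
#'
#' Amplitude comparisons between correction conditions must use the same
#' trials; this errors if the two masks differ in kept trials or
#' provenance.
#'
#' @param mask_a,mask_b `epoch_mask` objects.
#' @return `TRUE`, invisibly.
#' @export
check_same_mask <- function(mask_a, mask_b) {
  if (!identical(mask_a$keep, mask_b$keep) ||
      !identical(mask_a$provenance, mask_b$provenance))
    stop("epoch masks differ between conditions; comparisons must share one frozen mask")
  invisible(TRUE)
}

#' Write an epoch mask as CSV
#' @param mask an `epoch_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(data.frame(trial_index = seq_along(mask$keep),
                              keep = mask$keep, reason = mask$reason),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
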