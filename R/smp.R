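# Saccade muscle potential (SMP) correction.  The extra-ocular muscles
# generate a stereotyped potential at each (micro)saccade that volume-
# conducts into scalp channels.  With dedicated reference electrodes at the
# left and right eye corners, each EEG channel is regressed jointly on the
# two reference signals and the weighted references are subtracted.

#' Fit the saccade-muscle-potential regression model
#'
#' Joint ordinary least squares of every EEG channel on the left and right
#' eye-corner reference channels (plus an intercept, which is not
#' subtracted).  If the two references are nearly collinear (|r| > 0.999)
#' the fit falls back to their mean, splitting the weight equally.
#'
#' @param rec an [recording()] containing the reference channels.
#' @param ref_labels character(2): left and right eye-corner channel labels.
#' @param constrain_average if `TRUE`, regress on the plain average of the
#'   two references (one free coefficient) instead of two free
#'   coefficients — the literal "weighted average" reading.
#' @return an object of class `smp_model`: per-channel weights, standard
#'   errors and the reference labels.
#' @export
fit_smp <- function(rec, ref_labels, constrain_average = FALSE) {
  stopifnot(length(ref_labels) == 2L)
  L <- get_channel(rec, ref_labels[1L])
  R <- get_channel(rec, ref_labels[2L])
  if (stats::sd(L) == 0 || stats::sd(R) == 0)
    stop("constant SMP reference channel: ", ref_labels[which(c(stats::sd(L), stats::sd(R)) == 0)][1L])
  collinear <- abs(stats::cor(L, R)) > 0.999
  if (collinear && !constrain_average)
    message("SMP references nearly collinear; regressing on their mean")
  use_mean <- constrain_average || collinear
  targets <- setdiff(rec$channel_labels, ref_labels)
  wts <- matrix(0, nrow = length(targets), ncol = 2L,
                dimnames = list(targets, c("left", "right")))
  ses <- wts
  X <- if (use_mean) cbind(1, (L + R) / 2) else cbind(1, L, R)
  XtXinv <- solve(crossprod(X))
  for (lab in targets) {
    y <- get_channel(rec, lab)
    fit <- stats::.lm.fit(X, y)
    co <- fit$coefficients
    dof <- length(y) - ncol(X)
    s2 <- sum(fit$residuals^2) / dof
    se <- sqrt(diag(XtXinv) * s2)
    if (use_mean) {
      wts[lab, ] <- co[2L] / 2
      ses[lab, ] <- se[2L] / 2
    } else {
      wts[lab, ] <- co[2:3]
      ses[lab, ] <- se[2:3]
    }
  }
  structure(list(ref_labels = ref_labels, weights = wts, se = ses,
                 n = ncol(rec$samples), fs = rec$fs,
                 constrained = use_mean),
            class = "smp_model")
}

#' Subtract the fitted saccade muscle potential
#'
#' Corrected channel = channel - wL * left_ref - wR * right_ref.  The
#' reference channels themselves pass through unchanged for audit.
#'
#' @param rec an [recording()] with the same sampling rate and length the
#'   model was fitted on.
#' @param model an `smp_model` from [fit_smp()].
#' @return corrected [recording()].
#' @export
apply_smp <- function(rec, model) {
  if (ncol(rec$samples) != model$n || rec$fs != model$fs)
    stop("recording length/fs does not match the fitted SMP model")
  L <- get_channel(rec, model$ref_labels[1L])
  R <- get_channel(rec, model$ref_labels[2L])
  out <- rec
  for (lab in rownames(model$weights)) {
    if (!lab %in% rec$channel_labels) next
    x <- get_channel(rec, lab) -
      model$weights[lab, "left"] * L - model$weights[lab, "right"] * R
    out <- set_channel(out, lab, x)
  }
  out
}
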