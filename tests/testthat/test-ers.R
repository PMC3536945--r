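test_that("baseline windows respect the previous press", {
  # generous gap: full 1 s baseline
  expect_equal(baseline_window(c(1, 2.53), 2), c(1.53, 2.53))
  # 0.8 s gap: window starts 250 ms after the previous press
  bw <- baseline_window(c(1, 1.8), 2)
  expect_equal(bw, c(1.25, 1.8))
  expect_equal(diff(bw), 0.55)
  # gap equal to the guard: trial excluded
  expect_null(baseline_window(c(1, 1.25), 2))
  # never overlaps the previous trial's 0-250 ms peak window
  set.seed(18)
  times <- cumsum(runif(50, 0.2, 2))
  for (i in 2:50) {
    bw <- baseline_window(times, i)
    if (!is.null(bw)) expect_gte(bw[1], times[i - 1] + 0.25)
  }
})

test_that("ers_test matches the reference t implementation exactly", {
  set.seed(19)
  pk <- rnorm(12, 1); bl <- rnorm(12)
  res <- ers_test(pk, bl)
  ref <- t.test(pk, bl, paired = TRUE, alternative = "greater")
  expect_lt(abs(res$t - unname(ref$statistic)), 1e-10)
  expect_lt(abs(res$p - ref$p.value), 1e-10)
  res2 <- ers_test(pk, bl, tail = "two")
  ref2 <- t.test(pk, bl, paired = TRUE)
  expect_lt(abs(res2$p - ref2$p.value), 1e-10)
  # all-equal peak and baseline: t = 0, one-tailed p = 0.5
  resz <- ers_test(rep(1, 5), rep(1, 5))
  expect_equal(resz$t, 0)
  expect_equal(resz$p, 0.5)
  expect_true(resz$degenerate)
  # mask restricts the trials used
  mask <- build_mask(c(rep(0.1, 12), 0.9, 0.9))
  resm <- ers_test(c(pk, 99, 99), c(bl, 0, 0), mask)
  expect_equal(resm$n, 12)
  expect_equal(resm$t, res$t)
})

test_that("ers_test has power on injected effects", {
  # effect size d ~ 1 at n = 40 trials: p < 0.01 in >= 90% of seeded runs
  set.seed(20)
  hits <- 0
  for (i in 1:100) {
    d <- rnorm(40, mean = 1, sd = 1)
    hits <- hits + (ers_test(d, numeric(40))$p < 0.01)
  }
  expect_gte(hits / 100, 0.90)
})

test_that("correction_effect_test enforces masks and directions", {
  set.seed(21)
  pre <- rnorm(30, 1.2); post <- pre - rnorm(30, 0.2, 0.05)
  mask <- build_mask(rep(0.1, 30))
  res <- correction_effect_test(pre, post, mask_pre = mask, mask_post = mask)
  expect_lt(res$baseline_test$p, 0.01)   # reduction detected, one-tailed
  # identical conditions: t = 0
  res0 <- correction_effect_test(pre, pre)
  expect_equal(res0$baseline_test$t, 0)
  # differing masks refuse to compare
  mask2 <- mask; mask2$keep[1] <- FALSE
  expect_error(correction_effect_test(pre, post, mask_pre = mask,
                                      mask_post = mask2), "frozen")
  # peak test is two-tailed
  pk_pre <- rnorm(30); pk_post <- pk_pre
  res2 <- correction_effect_test(pre, post, pk_pre, pk_post,
                                 mask_pre = mask, mask_post = mask)
  expect_equal(res2$peak_test$tail, "two")
})

test_that("topography Z scores localise an injected effect", {
  set.seed(22)
  ers <- matrix(rnorm(70 * 5, 0, 0.02), 70, 5,
                dimnames = list(NULL, c("C3-CZ", "C4-CZ", "TP7-CPZ",
                                        "TP8-CPZ", "PZ-CZ")))
  expect_lt(abs(topography_z(ers)$z[["PZ-CZ"]]), 1)   # null ~ 0
  ers[, "C3-CZ"] <- ers[, "C3-CZ"] + 0.02
  tz <- topography_z(ers)
  expect_equal(names(which.max(abs(tz$z))), "C3-CZ")
  # zero-SD derivation reported missing
  ers[, 2] <- 0
  expect_message(tz2 <- topography_z(ers), "zero SD")
  expect_true(is.na(tz2$z[["C4-CZ"]]))
  # across-subject average
  avg <- average_topographies(list(tz, tz))
  expect_equal(avg$z[["C3-CZ"]], tz$z[["C3-CZ"]])
})

test_that("trial_band_amplitudes picks up an event-locked band increase", {
  spec <- quiet_spec(n_events = 15, spike_rate_hz = 0, burst_amp_uv = 2,
                     seed = 23)
  sim <- simulate_eeg(spec)
  tb <- trial_band_amplitudes(sim$recording, sim$events, "C3", "CZ")
  expect_equal(nrow(tb), 15)
  et <- ers_test(tb$peak, tb$baseline)
  expect_lt(et$p, 0.01)
  expect_gt(et$mean_ers, 0)
})
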