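test_that("the adaptive threshold follows a*mean + b with cap and bound", {
  cfg <- rejection_config()
  # mean 0.10 -> 1.5*0.10 + 0.06 = 0.21
  expect_equal(compute_threshold(rep(0.10, 70), cfg), 0.21)
  # mean 0 -> offset only
  expect_equal(compute_threshold(rep(0, 70), cfg), 0.06)
  # mean 0.50 -> raw 0.81 capped at 0.40 (amplitudes heterogeneous so the
  # 30/70 bound does not engage: most trials sit below the cap)
  thr <- compute_threshold(c(rep(0.39, 60), rep(1.16, 10)), cfg)
  expect_equal(thr, 0.4)
  # monotone non-decreasing in the mean until the cap
  thrs <- vapply(seq(0, 0.3, by = 0.02),
                 function(m) compute_threshold(rep(m, 70), cfg), 0)
  expect_true(all(diff(thrs) >= 0))
  expect_true(all(thrs <= 0.4 + 1e-12))
})

test_that("the 30-of-70 rejection bound raises the threshold", {
  cfg <- rejection_config()
  # 40 contaminated trials above any capped threshold
  amps <- c(rep(0.05, 30), rep(1.0, 35), rep(2.0, 5))
  expect_message(thr <- compute_threshold(amps, cfg), "raised")
  expect_lte(sum(amps > thr), 30)
  mask <- suppressMessages(build_mask(amps, cfg))
  expect_lte(sum(!mask$keep), 30)
})

test_that("build_mask rejects exactly the separated contaminated trials", {
  set.seed(16)
  amps <- c(runif(60, 0.05, 0.12), runif(10, 0.3, 0.39))
  mask <- build_mask(amps, rejection_config())
  expect_identical(which(!mask$keep), 61:70)
  expect_equal(mask$provenance, "post_smp_pre_emg")
  # all-equal amplitudes below threshold: everything kept
  mask2 <- build_mask(rep(0.1, 70))
  expect_true(all(mask2$keep))
  # determinism
  expect_identical(build_mask(amps), build_mask(amps))
})

test_that("the 6 SD anomaly rule rejects only extreme trials, once", {
  set.seed(17)
  maxg <- rnorm(70, 0.2, 0.01)
  mask <- build_mask(rep(0.1, 70))
  maxg[35] <- 0.2 + 8 * 0.01
  m2 <- anomaly_reject(maxg, mask, rejection_config())
  expect_false(m2$keep[35])
  expect_equal(m2$reason[35], "anomaly_6sd")
  # Gaussian maxima at n = 70: 6 SD exceedances are essentially absent
  extra <- 0
  for (i in 1:100) {
    g <- rnorm(70)
    mm <- anomaly_reject(g, build_mask(rep(0.1, 70)), rejection_config())
    extra <- extra + sum(!mm$keep)
  }
  expect_lte(extra, 1)
  # fewer than 3 kept trials: rule skipped with a warning
  tiny <- build_mask(rep(0.1, 5))
  tiny$keep[3:5] <- FALSE
  expect_warning(anomaly_reject(rnorm(5), tiny, rejection_config()), "skipped")
})

test_that("cross-condition comparisons must share the frozen mask", {
  a <- build_mask(rep(0.1, 10))
  b <- a
  expect_silent(check_same_mask(a, b))
  b$keep[3] <- FALSE
  expect_error(check_same_mask(a, b), "frozen")
  c_ <- build_mask(rep(0.1, 10), provenance = "other")
  expect_error(check_same_mask(a, c_), "frozen")
})

test_that("masks serialise as trial/keep/reason CSV", {
  mask <- build_mask(c(rep(0.1, 8), 0.9, 0.95))
  p <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(mask, p)
  d <- read.csv(p)
  expect_equal(nrow(d), 10)
  expect_equal(sum(!d$keep), 2)
})
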