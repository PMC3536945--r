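make_smp_rec <- function(wl = 0.2, wr = 0, n = 2000 * 90, fs = 2000, seed = 1) {
  set.seed(seed)
  L <- rnorm(n); R <- rnorm(n)
  brain <- rnorm(n, sd = 3)
  recording(rbind(C3 = wl * L + wr * R + brain, SMPL = L, SMPR = R),
            fs, c("C3", "SMPL", "SMPR"))
}

test_that("fit_smp recovers known mixing weights", {
  rec <- make_smp_rec(wl = 0.2, wr = 0)
  mod <- fit_smp(rec, c("SMPL", "SMPR"))
  expect_lt(abs(mod$weights["C3", "left"] - 0.2), 0.02)
  expect_lt(abs(mod$weights["C3", "right"]), 0.02)
  # null channel: weights within 3 standard errors of zero
  rec0 <- make_smp_rec(wl = 0, wr = 0, seed = 2)
  mod0 <- fit_smp(rec0, c("SMPL", "SMPR"))
  expect_true(all(abs(mod0$weights["C3", ]) < 3 * mod0$se["C3", ]))
  # exact copy of one reference
  set.seed(3)
  L <- rnorm(5000); R <- rnorm(5000)
  rec1 <- recording(rbind(C3 = R, SMPL = L, SMPR = R), 1000,
                    c("C3", "SMPL", "SMPR"))
  mod1 <- fit_smp(rec1, c("SMPL", "SMPR"))
  expect_equal(unname(mod1$weights["C3", "right"]), 1, tolerance = 1e-8)
  corr <- apply_smp(rec1, mod1)
  expect_lt(max(abs(get_channel(corr, "C3"))), 1e-8)
})

test_that("fit_smp rejects constant references, handles collinear ones", {
  rec <- make_smp_rec()
  rec$samples["SMPR", ] <- 5
  expect_error(fit_smp(rec, c("SMPL", "SMPR")), "constant")
  set.seed(4)
  L <- rnorm(5000)
  rec2 <- recording(rbind(C3 = 0.3 * L + rnorm(5000), SMPL = L,
                          SMPR = L + rnorm(5000, sd = 1e-4)),
                    1000, c("C3", "SMPL", "SMPR"))
  expect_message(mod <- fit_smp(rec2, c("SMPL", "SMPR")), "collinear")
  expect_lt(abs(sum(mod$weights["C3", ]) - 0.3), 0.05)
})

test_that("apply_smp subtracts the weighted references and is idempotent", {
  rec <- make_smp_rec(wl = 0.25, wr = 0.1, seed = 5)
  mod <- fit_smp(rec, c("SMPL", "SMPR"))
  corr <- apply_smp(rec, mod)
  # references pass through unchanged
  expect_identical(get_channel(corr, "SMPL"), get_channel(rec, "SMPL"))
  # injected SMP energy removed: residual correlation with refs ~ 0
  expect_lt(abs(cor(get_channel(corr, "C3"), get_channel(rec, "SMPL"))), 1e-6)
  # refit on corrected data gives ~zero weights
  mod2 <- fit_smp(corr, c("SMPL", "SMPR"))
  expect_true(all(abs(mod2$weights["C3", ]) < 1e-6))
  # zero-weight model leaves the recording identical
  modz <- mod
  modz$weights[] <- 0
  expect_identical(apply_smp(rec, modz)$samples, rec$samples)
  # length mismatch is an error
  shorter <- recording(rec$samples[, 1:100], rec$fs, rec$channel_labels)
  expect_error(apply_smp(shorter, mod), "match")
})

test_that("SMP correction leaves an uncorrelated gamma burst intact", {
  fs <- 2000; n <- fs * 20
  set.seed(6)
  L <- rnorm(n); R <- rnorm(n)
  burst <- numeric(n)
  tgrid <- (0:(fs / 2 - 1)) / fs
  for (s in seq(1, 18, by = 1)) {
    i0 <- s * fs
    burst[i0:(i0 + fs / 2 - 1)] <- burst[i0:(i0 + fs / 2 - 1)] +
      0.5 * sin(2 * pi * 75 * tgrid)
  }
  x <- 0.2 * L + rnorm(n, sd = 3) + burst
  rec <- recording(rbind(C3 = x, SMPL = L, SMPR = R), fs,
                   c("C3", "SMPL", "SMPR"))
  corr <- apply_smp(rec, fit_smp(rec, c("SMPL", "SMPR")))
  g0 <- gaborclean:::band_rms(x, fs, 65, 85)
  g1 <- gaborclean:::band_rms(get_channel(corr, "C3"), fs, 65, 85)
  expect_lt(abs(g1 / g0 - 1), 0.01)
})
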