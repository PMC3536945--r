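fs <- 2000

test_that("extract_fundamental returns a unit quadrature pair", {
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 50 * t)
  fund <- extract_fundamental(x, fs)
  int <- (2 * fs):(8 * fs)   # away from filter edges
  expect_lt(max(abs(fund$sine[int] - sin(2 * pi * 50 * t[int]))), 1e-3)
  expect_lt(max(abs(fund$cosine[int] - cos(2 * pi * 50 * t[int]))), 1e-3)
  # white noise with no mains line is rejected
  set.seed(1)
  expect_error(extract_fundamental(rnorm(fs * 5), fs), "no mains component")
  expect_error(extract_fundamental(numeric(fs), fs), "no mains component")
})

test_that("the quadrature pair tracks slow mains frequency wander", {
  t <- (0:(fs * 20 - 1)) / fs
  # +/- 0.05 Hz sinusoidal wander
  phase <- 2 * pi * 50 * t + (0.05 / 0.02) * sin(2 * pi * 0.02 * t)
  fund <- extract_fundamental(sin(phase), fs)
  int <- (3 * fs):(17 * fs)
  est_phase <- atan2(fund$sine[int], fund$cosine[int])   # = phase mod 2pi
  err <- (est_phase - phase[int] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(err)), 0.05)
})

test_that("harmonic recursion reproduces analytic harmonics", {
  t <- (0:(fs * 4 - 1)) / fs
  s <- sin(2 * pi * 50 * t); c_ <- cos(2 * pi * 50 * t)
  # K = 1 returns the pair unchanged
  B1 <- build_harmonics(s, c_, 1)
  expect_identical(B1[, 1], s)
  expect_identical(B1[, 2], c_)
  B3 <- build_harmonics(s, c_, 3)
  expect_lt(max(abs(B3[, 3] - sin(2 * pi * 100 * t))), 1e-6)
  expect_lt(max(abs(B3[, 4] - cos(2 * pi * 100 * t))), 1e-6)
  # pairwise orthogonality over whole cycles
  int <- 1:(fs * 2)           # 100 cycles of 50 Hz
  G <- crossprod(B3[int, ])
  nrm <- sqrt(diag(G))
  C <- G / outer(nrm, nrm)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-3)
  expect_error(build_harmonics(s, c_, 25, f0 = 50, fs = fs), "Nyquist")
})

test_that("cancel_powerline removes injected line and harmonics", {
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  set.seed(1)
  mains <- sin(2 * pi * 50 * t + 0.7) + 0.3 * sin(2 * pi * 150 * t + 2.1)
  eeg <- gaborclean:::pink_noise(n, fs, 3, 1)
  rec <- recording(rbind(C3 = eeg + 1.1 * mains,
                         MAINS = mains + rnorm(n, sd = 0.02)),
                   fs, c("C3", "MAINS"))
  out <- cancel_powerline(rec, noise_ref = "MAINS", K = 3)
  x0 <- get_channel(rec, "C3"); x1 <- get_channel(out$recording, "C3")
  bp <- function(x, f) gaborclean:::band_rms(x, fs, f - 1, f + 1)^2
  # removed power vs injected line power, per component
  for (fh in c(50, 150)) {
    injected <- bp(1.1 * mains, fh)
    removed <- bp(x0, fh) - bp(x1, fh)
    expect_gt(removed / injected, 0.99)
  }
  # residual orthogonal to the basis (projection property)
  fund <- extract_fundamental(get_channel(rec, "MAINS"), fs)
  B <- build_harmonics(fund$sine, fund$cosine, 3)
  resid <- x1 - mean(x1)
  ip <- abs(crossprod(B, resid)) / (sqrt(colSums(B^2)) * sqrt(sum(resid^2)))
  expect_lt(max(ip), 1e-6)
  # projection never increases total power (after mean removal)
  expect_lte(sum((x1 - mean(x1))^2), sum((x0 - mean(x0))^2) * (1 + 1e-12))
})

test_that("channels without mains content are nearly untouched", {
  # the regression floor is sqrt(p/n) of the channel RMS, so use a long span
  n <- fs * 80
  t <- (0:(n - 1)) / fs
  set.seed(2)
  clean <- gaborclean:::pink_noise(n, fs, 3, 1)
  rec <- recording(rbind(C3 = clean, MAINS = sin(2 * pi * 50 * t)),
                   fs, c("C3", "MAINS"))
  out <- cancel_powerline(rec, noise_ref = "MAINS", K = 3)
  x1 <- get_channel(out$recording, "C3")
  expect_lt(sqrt(mean((x1 - clean)^2)) / sqrt(mean(clean^2)), 0.01)
})
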