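fs5 <- 5000
tg5 <- (0:(fs5 - 1)) / fs5

test_that("gabor_waveform has the expected symmetries and energy", {
  tgrid <- seq(-0.05, 0.05, by = 1 / fs5)
  g0 <- gabor_waveform(tgrid, 0, 0.002, 143, phi = 0, A = 2)
  expect_equal(g0[tgrid == 0], 0)
  expect_equal(g0, -rev(g0))                       # odd about t0
  g90 <- gabor_waveform(tgrid, 0, 0.002, 143, phi = pi / 2, A = 2)
  expect_equal(g90[tgrid == 0], 2)
  expect_equal(g90, rev(g90))                      # even about t0
  expect_error(gabor_waveform(tgrid, 0, -1, 143), "sigma")
  # discrete energy vs closed form for the cosine-phase atom:
  # integral g^2 = A^2 sigma sqrt(pi)/2 (1 + exp(-(2 pi f sigma)^2))
  sg <- 0.002; f <- 143
  analytic <- sg * sqrt(pi) / 2 * (1 + exp(-(2 * pi * f * sg)^2))
  discrete <- sum(gabor_waveform(tgrid, 0, sg, f, pi / 2, 1)^2) / fs5
  expect_lt(abs(discrete / analytic - 1), 0.001)
})

test_that("detect_candidates finds sharp changes and honours the threshold", {
  cfg <- detection_config(fs5)
  expect_identical(detect_candidates(numeric(fs5), fs5, cfg), integer(0))
  x <- gabor_waveform(tg5, 0.5, 0.0015, 143, phi = 0, A = 20)
  cand <- detect_candidates(x, fs5, cfg)
  expect_length(cand, 1)
  expect_lt(abs(cand - (0.5 * fs5 + 1)) / fs5, 0.001)
  # brute-force oracle: the candidate's 3.5 ms change is the global max
  nd <- round(0.0035 * fs5)
  d <- abs(x[(nd + 1):fs5] - x[1:(fs5 - nd)])
  expect_lt(abs(cand - which.max(d)), nd)
  # spike scaled so its largest 3.5 ms change is 6.9 muV -> below 7 muV
  x2 <- x * 6.9 / max(d)
  expect_identical(detect_candidates(x2, fs5, cfg), integer(0))
  expect_error(detect_candidates(numeric(10), fs5, cfg), "shorter")
})

test_that("lowering v_thresh never loses candidates (monotonicity)", {
  set.seed(8)
  x <- gaborclean:::pink_noise(fs5 * 2, fs5, 4, 1) +
    gabor_waveform((0:(2 * fs5 - 1)) / fs5, 0.7, 0.002, 143, 1, 25)
  counts <- vapply(c(9, 7, 5, 4), function(v)
    length(detect_candidates(x, fs5, detection_config(fs5, v_thresh = v))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("locate_center pins the envelope centre and gates on d1/d3", {
  cfg <- detection_config(fs5)
  x <- gabor_waveform(tg5, 0.5, 0.002, 143, phi = 0, A = 15)
  loc <- locate_center(x, fs5, round(0.5 * fs5) + 1L, cfg)
  # the offset d1/d3 pairing bounds the correlation near -cos(2 pi f / fs),
  # and for an odd-phase atom the most sinusoid-like point sits up to ~1 ms
  # off the envelope centre; the sub-sample refinement recovers the rest
  expect_lt(loc$corr, -0.95)
  expect_lte(abs(loc$center - (0.5 * fs5 + 1)), round(0.002 * fs5))
  # white noise is rejected by the gate in >= 95% of seeded trials
  set.seed(9)
  rej <- 0
  for (i in 1:200) {
    xn <- rnorm(2000)
    if (is.null(locate_center(xn, fs5, sample(200:1800, 1), cfg))) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.95)
})

test_that("sigma estimation inverts the gradient-ratio table", {
  cfg <- detection_config(fs5)
  # ratio table strictly monotone (decreasing) on the invertible branch
  tab <- gaborclean:::sigma_ratio_table(fs5, cfg$f, cfg$sigma_grid_ms)
  branch <- tab$ratio[tab$branch_start:length(tab$ratio)]
  expect_true(all(branch > 0))
  expect_true(all(diff(branch) < 0))
  # noiseless atom: estimate within one grid step
  x <- gabor_waveform(tg5, 0.5, 0.002, cfg$f, phi = 0, A = 15)
  sg <- estimate_sigma(x, fs5, round(0.5 * fs5) + 1L, cfg, refine = FALSE)
  expect_lt(abs(sg - 0.002), 0.05e-3 + 1e-9)
  # atom below the invertible branch: clamped to the grid minimum with a
  # warning (table-only mode)
  xs <- gabor_waveform(tg5, 0.5, 0.0003, cfg$f, phi = 0, A = 15)
  expect_warning(
    sgs <- estimate_sigma(xs, fs5, round(0.5 * fs5) + 1L, cfg, refine = FALSE),
    "clamped to grid minimum")
  expect_equal(sgs, min(cfg$sigma_grid_ms) / 1000)
})

test_that("refine_center climbs to the true centre and is a fixed point", {
  cfg <- detection_config(fs5)
  truth <- 0.5002
  x <- gabor_waveform(tg5, truth, 0.002, cfg$f, phi = 0.8, A = 15)
  sp <- refine_center(x, fs5, list(t0 = 0.5, sigma = 0.002, f = cfg$f), cfg)
  expect_lt(abs(sp$t0 - truth), 0.02e-3)
  # already-optimal start does not move
  sp2 <- refine_center(x, fs5, list(t0 = sp$t0, sigma = 0.002, f = cfg$f), cfg)
  expect_equal(sp2$t0, sp$t0)
  # default step size is 0.01 ms
  expect_equal(cfg$refine_step_s, 1e-5)
})

test_that("fit_amplitude_and_subtract is local and recovers amplitude", {
  cfg <- detection_config(fs5, extra_hf = FALSE)
  truth <- list(t0 = 0.5, sigma = 0.002, f = cfg$f)
  x <- gabor_waveform(tg5, 0.5, 0.002, cfg$f, phi = 1.0, A = 15)
  res <- fit_amplitude_and_subtract(x, fs5, truth, cfg)
  expect_equal(res$spike$A, 15, tolerance = 1e-6)
  expect_equal(res$spike$phi, 1.0, tolerance = 1e-6)
  # samples outside t0 +/- 4 sigma are bit-identical
  out <- abs(tg5 - 0.5) > 4 * 0.002 + 2 / fs5
  expect_identical(res$signal[out], x[out])
  # forced fit where there is no spike: tiny amplitude, tiny power change
  set.seed(10)
  noise <- gaborclean:::pink_noise(fs5, fs5, 2, 1)
  resn <- fit_amplitude_and_subtract(noise, fs5, truth, cfg)
  expect_lt(resn$spike$A, 2 * 2)
  expect_lt(abs(sum(resn$signal^2) / sum(noise^2) - 1), 0.01)
  # support window outside the signal is an error
  expect_error(
    fit_amplitude_and_subtract(x, fs5, list(t0 = 0.0005, sigma = 0.002, f = cfg$f), cfg),
    "support window")
})

test_that("reduce_emg's inventory explains the correction exactly", {
  sim <- simulate_eeg(quiet_spec(seed = 21))
  res <- reduce_emg(sim$recording, channels = "C3")
  n <- ncol(sim$recording$samples)
  recon <- spikes_waveform(res$spikes, n, sim$recording$fs, "C3")
  expect_lt(max(abs((get_channel(sim$recording, "C3") - recon) -
                      get_channel(res$recording, "C3"))), 1e-9)
  # untouched channel passes through bit-identically
  expect_identical(get_channel(res$recording, "CZ"),
                   get_channel(sim$recording, "CZ"))
})

test_that("amplitude and power reductions are consistent", {
  # 1 - amp_after/amp_before == 1 - sqrt(power_after/power_before)
  sim <- simulate_eeg(quiet_spec(seed = 22))
  res <- reduce_emg(sim$recording, channels = c("C3", "CZ"))
  for (ch in c("C3", "CZ")) {
    a0 <- gaborclean:::band_rms(get_channel(sim$recording, ch), 2000, 60, 130)
    a1 <- gaborclean:::band_rms(get_channel(res$recording, ch), 2000, 60, 130)
    amp_red <- 1 - a1 / a0
    pow_red <- 1 - a1^2 / a0^2
    expect_equal(amp_red, amp_reduction_from_power(pow_red), tolerance = 1e-10)
  }
})
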