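test_that("zero-amplitude components give an all-zero recording", {
  spec <- simulation_spec(channels = c("C3", "CZ"), n_events = 3,
                          pink_rms_uv = 0, mu_amp_uv = 0, mains_amp_uv = 0,
                          include_mains_channel = FALSE, spike_rate_hz = 0,
                          burst_amp_uv = 0, smp_rate_hz = 0,
                          include_smp_refs = FALSE, seed = 1)
  sim <- simulate_eeg(spec)
  expect_true(all(sim$recording$samples == 0))
  expect_equal(nrow(sim$truth$spikes), 0)
})

test_that("spike counts follow the Poisson process", {
  spec <- quiet_spec(n_events = 40, seed = 31)   # ~60 s at 5/s
  sim <- simulate_eeg(spec)
  dur <- ncol(sim$recording$samples) / sim$recording$fs
  lambda <- 5 * dur
  k <- sum(sim$truth$spikes$channel == "C3")
  expect_gte(k, qpois(0.005, lambda))
  expect_lte(k, qpois(0.995, lambda))
  # spike parameters within their declared ranges
  expect_true(all(sim$truth$spikes$amp_uv >= 8 & sim$truth$spikes$amp_uv <= 30))
  expect_true(all(sim$truth$spikes$sigma_ms >= 1 & sim$truth$spikes$sigma_ms <= 4))
})

test_that("press pacing matches the self-paced task", {
  spec <- simulation_spec(seed = 32)
  sim <- simulate_eeg(spec)
  expect_length(sim$events$times, 70)
  gaps <- diff(sim$events$times)
  expect_lt(abs(mean(gaps) - 1.53), 0.15)
})

test_that("same spec and seed give bit-identical output", {
  a <- simulate_eeg(quiet_spec(seed = 33))
  b <- simulate_eeg(quiet_spec(seed = 33))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$spikes, b$truth$spikes)
  c_ <- simulate_eeg(quiet_spec(seed = 34))
  expect_false(identical(a$recording$samples, c_$recording$samples))
})

test_that("energy bookkeeping: components add with vanishing cross terms", {
  # power of the sum ~ sum of component powers, over independent draws
  fs <- 2000; n <- fs * 30
  set.seed(35)
  pk <- gaborclean:::pink_noise(n, fs, 3, 1)
  mu <- 5 * sin(2 * pi * 10 * (0:(n - 1)) / fs + 1)
  total <- mean((pk + mu)^2)
  parts <- mean(pk^2) + mean(mu^2)
  expect_lt(abs(total / parts - 1), 0.05)
})

test_that("score_correction reports zero distortion for identity/oracle", {
  sim <- simulate_eeg(quiet_spec(seed = 36))
  # corrected == original with spikes injected: nothing removed
  sc <- score_correction(sim, sim$recording)
  expect_equal(sc$residual_spike_energy_frac, 1)   # all spike energy remains
  expect_equal(sc$false_modification_frac, 0)
  expect_equal(unname(sc$gamma_change_frac["C3"]) > 0, TRUE)
  # oracle subtraction of the truth atoms: zero residual, zero false mod
  clean <- sim$recording
  n <- ncol(clean$samples)
  for (ch in c("C3", "CZ"))
    clean <- gaborclean:::set_channel(clean, ch,
      get_channel(sim$recording, ch) -
        spikes_waveform(sim$truth$spikes, n, 2000, ch))
  sco <- score_correction(sim, clean)
  expect_lt(sco$residual_spike_energy_frac, 1e-20)
  expect_lt(max(abs(sco$gamma_change_frac)), 1e-12)
  # no spikes injected and corrected == original: all-zero metrics
  sim0 <- simulate_eeg(quiet_spec(spike_rate_hz = 0, seed = 37))
  sc0 <- score_correction(sim0, sim0$recording)
  expect_equal(sc0$residual_spike_energy_frac, 0)
  expect_equal(max(abs(sc0$gamma_change_frac)), 0)
})

test_that("reduce_emg on the default generator meets the module bounds", {
  sim <- simulate_eeg(quiet_spec(n_events = 20, seed = 38))
  res <- reduce_emg(sim$recording)
  sc <- score_correction(sim, res$recording, derivation = "C3")
  expect_lte(sc$residual_spike_energy_frac, 0.40)
  # 60-130 Hz amplitude comes down materially (cf. 15%+ at central sites)
  expect_gte(sc$band_reduction[["60-130"]], 0.15)
})
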