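test_that("window defaults follow the sampling rate", {
  expect_identical(default_window_samples(2000), 512L)
  expect_identical(default_window_samples(5000), 2048L)
  expect_equal(512 / 2000, 0.256)     # 256 ms
  expect_equal(2048 / 5000, 0.4096)   # 409.6 ms
})

test_that("an on-bin unit sinusoid reads 1 muV before /Hz scaling", {
  fs <- 5000
  fb <- fs * round(75 * 2048 / fs) / 2048        # nearest on-bin frequency
  x <- sin(2 * pi * fb * (0:(3 * fs - 1)) / fs)
  m <- sliding_fft_amplitude(x, fs, 2048, fmax = 140)
  mid <- nrow(m$amplitudes) %/% 2
  peak <- max(m$amplitudes[mid, ]) * fs / 2048   # undo /Hz
  expect_lt(abs(peak - 1), 0.01)
  expect_equal(m$freqs[which.max(m$amplitudes[mid, ])], fb)
  # zero signal gives an all-zero map
  z <- sliding_fft_amplitude(numeric(3 * fs), fs, 2048)
  expect_true(all(z$amplitudes == 0))
  expect_error(sliding_fft_amplitude(numeric(100), fs, 2048), "longer")
})

test_that("map invariants: non-negative, 5 ms steps, fs/N spacing", {
  set.seed(11)
  fs <- 2000
  m <- sliding_fft_amplitude(rnorm(fs * 3), fs)
  expect_true(all(m$amplitudes >= 0))
  expect_equal(unique(round(diff(m$times), 10)), 0.005)
  expect_equal(diff(m$freqs)[1], fs / 512)
})

test_that("band_amplitude averages inclusive band edges and is linear", {
  set.seed(12)
  fs <- 2000
  m <- sliding_fft_amplitude(rnorm(fs * 4), fs)
  bin_f <- m$freqs[40]
  expect_equal(band_amplitude(m, bin_f, bin_f), m$amplitudes[, 40])
  sel <- m$freqs >= 60 & m$freqs <= 130
  expect_equal(band_amplitude(m, 60, 130),
               rowMeans(m$amplitudes[, sel]))
  expect_error(band_amplitude(m, 61, 61.5), "bins")
  m2 <- m; m2$amplitudes <- 2 * m$amplitudes
  expect_equal(band_amplitude(m2, 60, 130), 2 * band_amplitude(m, 60, 130))
  # flat white spectrum: band mean close to overall mean
  expect_lt(abs(mean(band_amplitude(m, 100, 400)) /
                  mean(band_amplitude(m, 400, 700)) - 1), 0.05)
})

test_that("windowed spectra satisfy Parseval within 2%", {
  set.seed(13)
  fs <- 2000; win <- 512
  x <- rnorm(win)
  w <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / (win - 1)))
  xw <- x * w
  X <- fft(xw)
  spec_power <- sum(Mod(X)^2) / win
  expect_lt(abs(spec_power / sum(xw^2) - 1), 0.02)
})

test_that("the convolution band-series path equals the map path", {
  set.seed(14)
  fs <- 2000
  x <- gaborclean:::pink_noise(fs * 6, fs, 3, 1)
  m <- sliding_fft_amplitude(x, fs, 512)
  ref <- band_amplitude(m, 65, 85)
  fast <- gaborclean:::stft_band_series(x, fs, 512, f_lo = 65, f_hi = 85)
  expect_equal(fast$series, ref, tolerance = 1e-12)
  expect_equal(fast$times, m$times)
})

test_that("maps serialise with a JSON sidecar", {
  set.seed(15)
  m <- sliding_fft_amplitude(rnorm(2000), 1000, 256, fmax = 100)
  p <- withr::local_tempfile()
  write_tf_map(m, p)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$window_samples, 256)
  expect_equal(side$freqs, m$freqs)
  amp <- as.matrix(read.table(paste0(p, ".txt")))
  expect_equal(dim(amp), dim(m$amplitudes))
})
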