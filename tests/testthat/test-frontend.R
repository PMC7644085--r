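test_that("ERB band centers span 20-5000 Hz with equal ERB spacing", {
  ctr <- erb_centers(256, 20, 5000)
  expect_equal(ctr[1], 20)
  expect_equal(ctr[256], 5000)
  e <- hz_to_erb(ctr)
  expect_equal(diff(e), rep(diff(e)[1], 255), tolerance = 1e-10)
  expect_true(all(diff(ctr) > 0))
})

test_that("gammatone spectrogram localizes a pure tone and maps silence to zero", {
  fs <- 16000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tone <- waveform(sin(2 * pi * 1000 * t), fs)
  sp <- gammatone_spectrogram(tone, n_bands = 64)
  expect_equal(nrow(sp$values), 1000)
  expect_equal(ncol(sp$values), 64)
  expect_true(all(sp$values >= 0))
  # band with maximal time-averaged output is the one closest to 1 kHz
  ctr <- erb_centers(64, 20, 5000)             # independent center grid
  expect_equal(which.max(colMeans(sp$values)),
               which.min(abs(ctr - 1000)))

  silence <- waveform(rep(0, fs), fs)
  sp0 <- gammatone_spectrogram(silence, n_bands = 16)
  expect_equal(max(abs(sp0$values)), 0)
  expect_equal(dim(sp0$values), c(1000L, 16L))
})

test_that("gammatone spectrogram rejects undersampled or empty input", {
  expect_error(gammatone_spectrogram(waveform(rnorm(100), 8000)),
               "Nyquist")
  expect_error(waveform(numeric(0), 1000), "empty")
})

test_that("edge detector is silent for constant input after the transient", {
  cfg <- edge_detector_config()
  const <- spec_of(matrix(5, 2000, 3), rate = 1000)
  on <- detect_edges(const, cfg)
  span <- max(round(cumsum(seq(cfg$tau_min, cfg$tau_max,
                               length.out = cfg$n_delays))))
  expect_equal(max(abs(on$values[(span + 2):2000, ])), 0)
  expect_identical(on$role, "onset")
})

test_that("a step onset yields one event and an offset yields none", {
  cfg <- edge_detector_config()
  x <- matrix(0, 3000, 1)
  t0 <- 1000; t1 <- 2000
  x[t0:(t1 - 1), 1] <- 4
  on <- detect_edges(spec_of(x, rate = 1000), cfg)
  v <- on$values[, 1]
  span <- 0.040 * 1000                         # total delay-layer span
  pos <- which(v > 1e-12)
  expect_true(all(pos >= t0 & pos <= t0 + span + 1))
  # one contiguous run
  expect_equal(length(unique(cumsum(c(1, diff(pos) != 1)))), 1L)
  # offset region silent
  expect_equal(max(v[(t1 - 1):(t1 + span + 5)]), 0)
})

test_that("edge detector output is nonnegative and translation equivariant", {
  cfg <- edge_detector_config()
  set.seed(3)
  v <- matrix(rexp(4000), 2000, 2)
  sp <- spec_of(v, rate = 1000)
  on <- detect_edges(sp, cfg)
  expect_true(all(on$values >= 0))
  k <- 57
  shifted <- rbind(matrix(0, k, 2), v[1:(2000 - k), ])
  on_sh <- detect_edges(spec_of(shifted, rate = 1000), cfg)
  # interior region: shifting input by k shifts output by k
  expect_equal(on_sh$values[(k + 101):2000, ],
               on$values[101:(2000 - k), ], tolerance = 1e-12)
})

test_that("amplitude scaling never decreases the response to a step", {
  # for step-family inputs the saturating nonlinearity composed with the
  # positive partial sums of the receptive field is monotone in amplitude
  cfg <- edge_detector_config()
  amps <- c(0.5, 1, 2, 4, 8, 16, 64)
  vals <- sapply(amps, function(a) {
    x <- matrix(0, 500, 1); x[200:500, 1] <- a
    max(detect_edges(spec_of(x, rate = 1000), cfg)$values)
  })
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("edge detector rejects invalid configurations and rates", {
  expect_error(edge_detector_config(n_delays = 1), "n_delays")
  expect_error(edge_detector_config(tau_min = 0), "tau_min")
  expect_error(edge_detector_config(saturation_c = -1), "saturation_c")
  expect_error(edge_detector_config(rf_sd = 0), "rf_sd")
  low <- spec_of(matrix(1, 100, 1), rate = 50)
  expect_error(detect_edges(low), "rate too low")
  on <- spec_of(matrix(1, 100, 1), rate = 1000, role = "onset")
  expect_error(detect_edges(on), "envelope")
})

test_that("band binning drops low bands, conserves mass, preserves zeros", {
  centers <- erb_centers(40, 50, 5000)
  set.seed(4)
  v <- matrix(rexp(200 * 40), 200, 40)
  sp <- spectrogram(v, 1000, centers, "envelope")
  b <- bin_bands(sp, n_bins = 8, fmin_bin = 100)
  expect_equal(ncol(b$values), 8)
  # mass over retained bands is conserved (sum binning)
  keep <- centers >= 100
  expect_equal(rowSums(b$values), rowSums(v[, keep]), tolerance = 1e-12)
  # independent per-group construction agrees
  e <- hz_to_erb(centers[keep])
  edges <- seq(e[1], e[length(e)], length.out = 9)
  grp <- pmin(findInterval(e, edges, rightmost.closed = TRUE), 8)
  for (g in 1:8)
    expect_equal(b$values[, g], rowSums(v[, keep][, grp == g, drop = FALSE]))

  # all-zero input stays zero; energy only below the cutoff vanishes
  z <- bin_bands(spectrogram(matrix(0, 10, 40), 1000, centers, "envelope"))
  expect_equal(max(abs(z$values)), 0)
  low_only <- matrix(0, 10, 40); low_only[, 1] <- 7   # 50 Hz band
  lo <- bin_bands(spectrogram(low_only, 1000, centers, "envelope"))
  expect_equal(max(abs(lo$values)), 0)
  expect_error(bin_bands(spectrogram(matrix(1, 5, 6),
                                     1000, centers[1:6], "envelope"), 8),
               "fewer")
})

test_that("downsampling preserves duration, constants and nonnegativity", {
  sp <- spec_of(matrix(3.7, 60000, 2), rate = 1000)
  dn <- resample_series(sp, 100)
  expect_equal(nrow(dn$values), 6000)
  expect_equal(dn$rate, 100)
  expect_equal(max(abs(dn$values - 3.7)), 0, tolerance = 1e-9)
  expect_error(resample_series(dn, 1000), "downsample")
  expect_error(resample_series(sp, 300), "divide")
})

test_that("band-limited content survives a down/up round trip", {
  skip_if_not_installed("signal")
  n <- 4000
  # strictly band-limited content, well below the 50 Hz output Nyquist
  t <- (0:(n - 1)) / 1000
  x <- 3 + sin(2 * pi * 3.7 * t) + 0.7 * sin(2 * pi * 11 * t + 1) +
    0.5 * sin(2 * pi * 23 * t + 2)
  sp <- spec_of(matrix(x, ncol = 1), rate = 1000)
  dn <- resample_series(sp, 100)
  up <- signal::resample(dn$values[, 1], 10, 1)   # independent resampler
  core <- 500:3500
  rel <- sqrt(mean((up[core] - x[core])^2)) / sqrt(mean(x[core]^2))
  expect_lt(rel, 0.01)
})

test_that("sinc upsampling reproduces original samples exactly", {
  set.seed(6)
  x <- rnorm(50)
  up <- upsample_sinc(x, 5)
  expect_equal(length(up), 49 * 5 + 1)
  expect_equal(up[seq(1, length(up), by = 5)], x, tolerance = 1e-9)
})

test_that("WAV round trip preserves samples and rate", {
  set.seed(7)
  path <- withr::local_tempfile(fileext = ".wav")
  x <- round(runif(1000, -0.8, 0.8) * 32767) / 32767
  write_wav(waveform(x, 8000), path)
  w <- read_wav(path)
  expect_equal(w$rate, 8000)
  expect_equal(w$samples, x * 32767 / 32768, tolerance = 2e-5)
})
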