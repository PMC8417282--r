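fs <- 1000
tvec <- function(dur) (0:(dur * fs - 1)) / fs

test_that("the 60 Hz notch removes line noise and preserves the passband", {
  x60 <- sin(2 * pi * 60 * tvec(10))
  y60 <- notch_60hz(x60, fs)
  expect_lt(sqrt(mean(y60^2)), 0.1 * sqrt(mean(x60^2)))

  x8 <- sin(2 * pi * 8 * tvec(10))
  y8 <- notch_60hz(x8, fs)
  expect_gt(cor(x8, y8), 0.99)

  expect_equal(notch_60hz(rep(0, 5000), fs), rep(0, 5000))
  expect_error(notch_60hz(x8, 100), "sample_rate")
})

test_that("spectrogram framing follows the window/overlap arithmetic", {
  x <- rnorm(10 * fs)
  fr <- compute_spectrogram(x, fs)  # 1000 ms window, 200 ms overlap
  expect_equal(ncol(fr$power), 12)  # hop 800 ms
  expect_equal(fr$freqs[2] - fr$freqs[1], 1)  # 1 Hz resolution
  expect_true(all(fr$power >= 0))
  expect_error(compute_spectrogram(rnorm(500), fs), "shorter")

  x8 <- sin(2 * pi * 8 * tvec(10))
  fr8 <- compute_spectrogram(x8, fs)
  expect_true(all(fr8$freqs[apply(fr8$power, 2, which.max)] == 8))
})

test_that("white-noise frame-mean PSD is flat over 1-100 Hz", {
  set.seed(1)
  fr <- compute_spectrogram(rnorm(300 * fs), fs)
  mp <- rowMeans(fr$power)
  sel <- fr$freqs >= 1 & fr$freqs <= 100
  expect_true(all(abs(mp[sel] / mean(mp[sel]) - 1) < 0.2))
})

test_that("session PSD normalizes to unit mass and concentrates planted peaks", {
  set.seed(2)
  x <- sin(2 * pi * 8 * tvec(60)) + 0.1 * rnorm(60 * fs)
  fr <- compute_spectrogram(x, fs)
  sp <- session_psd(fr, c(1, 100))
  expect_equal(sum(sp$norm_power), 1, tolerance = 1e-12)
  expect_gt(band_power(sp, band_def("theta")) * 8, 0.5)  # 8 theta bins hold most mass
  # determinism: identical signals give identical spectra
  sp2 <- session_psd(compute_spectrogram(x, fs), c(1, 100))
  expect_identical(sp$norm_power, sp2$norm_power)
})

test_that("band power and TD ratio follow their definitions", {
  flat <- structure(list(freqs = 1:100, norm_power = rep(1, 100),
                         norm_range = c(1, 100), lead_id = "l"),
                    class = "lead_spectrum")
  expect_equal(band_power(flat, band_def("theta")), 1)
  onepeak <- flat
  onepeak$norm_power <- ifelse(flat$freqs == 8, 1, 0)
  expect_equal(band_power(onepeak, band_def("delta")), 0)

  expect_equal(td_ratio(0.3, 0.1), 3)
  s <- runif(20) + 0.5
  expect_equal(td_ratio(s, s), rep(1, 20))
  expect_error(td_ratio(1, 0), "delta")
})

test_that("energy scales quadratically and the TD ratio is scale invariant", {
  set.seed(3)
  x <- sin(2 * pi * 8 * tvec(30)) + 0.5 * sin(2 * pi * 2.5 * tvec(30)) +
    0.2 * rnorm(30 * fs)
  fr1 <- compute_spectrogram(x, fs)
  fr3 <- compute_spectrogram(3 * x, fs)
  expect_equal(mean(band_power(fr3, band_def("theta"))),
               9 * mean(band_power(fr1, band_def("theta"))), tolerance = 1e-10)
  expect_equal(session_td_ratio(fr3), session_td_ratio(fr1), tolerance = 1e-10)
})

test_that("session PSD band masses agree with a single long periodogram", {
  set.seed(4)
  beh <- test_behavior()
  ph <- phenotype_params(theta_amp = 4, delta_amp = 2, noise_amp = 1)
  x <- synthesize_lead_signal(ph, beh)[1:(200 * fs)]
  fr <- compute_spectrogram(x, fs)
  sp <- session_psd(fr, c(1, 100))
  # oracle: one long periodogram over the same record
  n <- length(x)
  pw <- abs(fft(x - mean(x))[1:(n / 2 + 1)])^2
  f <- (0:(n / 2)) * fs / n
  mass <- function(lo, hi, p, fr) sum(p[fr >= lo & fr <= hi])
  tot <- mass(1, 100, pw, f)
  for (b in list(band_def("delta"), band_def("theta"))) {
    est <- sum(sp$norm_power[sp$freqs >= b$lo & sp$freqs <= b$hi])
    ora <- mass(b$lo, b$hi, pw, f) / tot
    expect_equal(est, ora, tolerance = 0.1)
  }
})

test_that("planted theta/delta balance separates the group presets", {
  coh <- effect_cohort()
  td <- sapply(coh, function(s) {
    prof <- session_spectral_profile(s)
    mean(prof$summary$td_ratio[prof$summary$area == "HPC"])
  })
  grp <- sapply(coh, function(s) s$leads$group[1])
  expect_gt(min(td[grp == "control"]), max(td[grp == "STZ"]))
})
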