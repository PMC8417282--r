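fs <- 1000

test_that("the analytic signal recovers sinusoid amplitude and phase", {
  t <- (0:9999) / fs
  x <- 3 * cos(2 * pi * 8 * t + 1)
  a <- analytic_signal(x)
  mid <- 2000:8000
  expect_equal(Mod(a)[mid], rep(3, length(mid)), tolerance = 1e-3)
  dphi <- diff(Arg(a)[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi), 2 * pi * 8 / fs, tolerance = 1e-6)
})

test_that("phase advances 2*pi per cycle and tone amplitude stays constant", {
  t <- (0:19999) / fs
  pa <- extract_phase_amplitude(cos(2 * pi * 8 * t), fs,
                                band_def("theta"), band_def("slow_gamma"))
  mid <- 5000:15000
  dphi <- diff(pa$phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  # 8 Hz: a full 2*pi in 125 ms
  expect_equal(mean(dphi) * 125, 2 * pi, tolerance = 1e-4)

  pa40 <- extract_phase_amplitude(cos(2 * pi * 40 * t), fs,
                                  band_def("theta"), band_def("slow_gamma"))
  amp <- pa40$amplitude[mid]
  expect_lt(sd(amp) / mean(amp), 0.02)
})

test_that("the modulation index hits its closed-form limits", {
  n <- 1800
  phase <- runif(n, -pi, pi)
  expect_equal(modulation_index(phase, rep(2.5, n)), 0, tolerance = 1e-12)

  # all amplitude mass in one bin
  one <- as.numeric(phase > -pi & phase <= -pi + 2 * pi / 18)
  expect_equal(modulation_index(phase, one), 1)

  # equal mass in exactly two bins -> 1 - ln 2 / ln 18
  grid <- rep(seq(-pi + pi / 18, pi - pi / 18, length.out = 18), each = 100)
  two <- as.numeric(grid < -pi + 2 * (2 * pi / 18))
  expect_equal(modulation_index(grid, two), 1 - log(2) / log(18),
               tolerance = 1e-12)

  expect_error(modulation_index(phase, rep(0, n)), "all-zero")
  expect_error(modulation_index(phase[1:100], rep(1, 100)), "too short")
})

test_that("MI matches a direct-sort binning oracle and is invariant to scaling and rotation", {
  set.seed(31)
  n <- 2000
  phase <- runif(n, -pi, pi)
  amp <- exp(rnorm(n)) * (1 + 0.5 * cos(phase))
  mi_oracle <- function(phase, amp, n_bins = 18) {
    cuts <- cut(phase, breaks = seq(-pi, pi, length.out = n_bins + 1),
                include.lowest = TRUE)
    pj <- sapply(split(amp, cuts), function(v) if (length(v)) mean(v) else 0)
    pj <- pj / sum(pj)
    h <- -sum(pj[pj > 0] * log(pj[pj > 0]))
    (log(n_bins) - h) / log(n_bins)
  }
  expect_equal(modulation_index(phase, amp), mi_oracle(phase, amp),
               tolerance = 1e-12)
  # amplitude scaling leaves MI unchanged
  expect_equal(modulation_index(phase, 100 * amp),
               modulation_index(phase, amp), tolerance = 1e-12)
  # rotating all phases by one bin width permutes P_j and preserves MI
  rot <- ((phase + 2 * pi / 18 + pi) %% (2 * pi)) - pi
  expect_equal(modulation_index(rot, amp), modulation_index(phase, amp),
               tolerance = 1e-12)
  expect_true(all(c(modulation_index(phase, amp),
                    modulation_index(rot, amp)) >= 0))
})

test_that("MI grows monotonically with the planted coupling depth", {
  beh <- test_behavior()
  mis <- sapply(c(0, 0.2, 0.4, 0.8), function(k) {
    ph <- phenotype_params(theta_amp = 3, delta_amp = 1, noise_amp = 1,
                           pac_depth = c(delta_theta = 0, theta_slow_gamma = k,
                                         theta_fast_gamma = 0))
    set.seed(40)  # matched noise realizations across depths
    x <- head(synthesize_lead_signal(ph, beh), 200000)
    pac_mi(x, fs, band_def("theta"), band_def("slow_gamma"))
  })
  expect_true(all(diff(mis) > 0))
  expect_gt(mis[4], 10 * mis[1])
})

test_that("white noise yields a flat comodulogram and planted coupling its argmax", {
  set.seed(41)
  wn <- rnorm(220 * fs)
  cm0 <- comodulogram(wn, fs, phase_freqs = c(4, 8, 12),
                      amp_freqs = c(30, 50, 80))
  expect_lt(max(cm0$mi), 0.01)
  expect_true(all(cm0$mi >= 0 & cm0$mi <= 1))

  beh <- test_behavior()
  ph <- phenotype_params(theta_amp = 3, delta_amp = 1, noise_amp = 1,
                         pac_depth = c(delta_theta = 0, theta_slow_gamma = 0.8,
                                       theta_fast_gamma = 0))
  set.seed(5)
  x <- head(synthesize_lead_signal(ph, beh), 220000)
  cm <- comodulogram(x, fs, phase_freqs = seq(2, 12, 2),
                     amp_freqs = seq(20, 100, 10))
  am <- which(cm$mi == max(cm$mi), arr.ind = TRUE)
  expect_equal(cm$amp_freqs[am[1]], 40)   # slow gamma carrier
  expect_equal(cm$phase_freqs[am[2]], 8)  # theta phase
})

test_that("session PAC summary averages an area's leads and separates the presets", {
  coh <- effect_cohort()
  ctrl <- coh[[which(sapply(coh, function(s) s$leads$group[1]) == "control")[1]]]
  stz <- coh[[which(sapply(coh, function(s) s$leads$group[1]) == "STZ")[1]]]
  p_ctrl <- session_pac_summary(ctrl)
  p_stz <- session_pac_summary(stz)
  expect_setequal(unique(p_ctrl$pair),
                  c("delta_theta", "theta_slow_gamma", "theta_fast_gamma"))
  expect_true(all(p_ctrl$n_leads == 8))
  m <- merge(p_ctrl, p_stz, by = c("area", "pair"), suffixes = c("_c", "_s"))
  # hippocampal hypercoupling is planted in every pair
  hpc <- m[m$area == "HPC", ]
  expect_true(all(hpc$mi_s > hpc$mi_c))
})
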