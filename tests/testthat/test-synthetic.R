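test_that("generated delays are uniform on [5,45] and outcomes follow the accuracy model", {
  set.seed(77)
  beh <- generate_behavior(2000, p_correct = c(short = 0.85, long = 0.60))
  tt <- build_trial_table(beh$events)
  expect_true(all(tt$delay_s >= 5 & tt$delay_s <= 45))
  expect_equal(mean(tt$delay_s), 25, tolerance = 0.03)
  # binomial oracle: long-delay accuracy near its planted probability
  acc_long <- mean(tt$outcome[tt$delay_category == "long"] == "correct")
  n_long <- sum(tt$delay_category == "long")
  expect_lt(abs(acc_long - 0.60), 3 * sqrt(0.6 * 0.4 / n_long))
  acc_short <- mean(tt$outcome[tt$delay_category == "short"] == "correct")
  expect_gt(acc_short - acc_long, 0.15)
})

test_that("animals are stationary during delays and move during runs", {
  beh <- test_behavior()
  sp <- running_speed(beh$positions)
  tt <- build_trial_table(beh$events)
  in_any <- function(t, lo, hi) {
    sapply(t, function(ti) any(ti >= lo & ti < hi))
  }
  delay_idx <- in_any(sp$t_s, tt$delay_start_s + 1, tt$trial_start_s - 1)
  run_idx <- in_any(sp$t_s, tt$trial_start_s + 1, tt$choice_time_s - 1)
  expect_lt(mean(sp$speed_cm_s[delay_idx]), 2)
  expect_gt(mean(sp$speed_cm_s[run_idx]), 15)
})

test_that("planted PAC raises the modulation index far above the unplanted value", {
  beh <- test_behavior()
  base <- phenotype_params(theta_amp = 3, delta_amp = 1, noise_amp = 1)
  planted <- phenotype_params(theta_amp = 3, delta_amp = 1, noise_amp = 1,
                              pac_depth = c(delta_theta = 0,
                                            theta_slow_gamma = 0,
                                            theta_fast_gamma = 0.8))
  set.seed(5); x0 <- head(synthesize_lead_signal(base, beh), 200000)
  set.seed(5); x1 <- head(synthesize_lead_signal(planted, beh), 200000)
  mi0 <- pac_mi(x0, 1000, band_def("theta"), band_def("fast_gamma"))
  mi1 <- pac_mi(x1, 1000, band_def("theta"), band_def("fast_gamma"))
  expect_gt(mi1, 10 * mi0)
})

test_that("speed coupling plants the configured correlation signs", {
  beh <- test_behavior()
  ph <- phenotype_params(theta_amp = 4, delta_amp = 2, noise_amp = 1,
                         speed_coupling = c(delta = -1, theta = 1))
  set.seed(6)
  x <- synthesize_lead_signal(ph, beh)
  fr <- compute_spectrogram(x, 1000)
  sp <- running_speed(beh$positions)
  r_theta <- speed_power_correlation(band_power(fr, band_def("theta")),
                                     fr$frame_times, sp)
  r_delta <- speed_power_correlation(band_power(fr, band_def("delta")),
                                     fr$frame_times, sp)
  expect_gt(r_theta, 0.5)
  expect_lt(r_delta, -0.5)
})

test_that("unplanted signals show neither PAC nor speed coupling", {
  beh <- test_behavior()
  ph <- phenotype_params(theta_amp = 2, delta_amp = 2, noise_amp = 1)
  set.seed(8)
  x <- head(synthesize_lead_signal(ph, beh), 200000)
  for (pair in list(c("delta", "theta"), c("theta", "slow_gamma"),
                    c("theta", "fast_gamma"))) {
    expect_lt(pac_mi(x, 1000, band_def(pair[1]), band_def(pair[2])), 0.003)
  }
})

test_that("the same seed reproduces a cohort exactly and lambda shifts clip to [0,1]", {
  cfg <- cohort_config(n_subjects = c(control = 1, STZ = 0),
                       n_sessions_per_subject = 1, n_trials = 3, seed = 500)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1[[1]]$signals, c2[[1]]$signals)
  expect_identical(c1[[1]]$events, c2[[1]]$events)

  ph <- phenotype_params(coherence_mix = 0.9, coherence_outcome_shift = 0.5,
                         coherence_long_multiplier = 2)
  ev <- data.frame(trial_index = 1, delay_start_s = 1, trial_start_s = 26,
                   choice_time_s = 29, return_time_s = 33, outcome = "error")
  lam <- lambda_series(ph, ev, 35000, 1000)
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(max(lam), 1)           # clipped during the error window
  expect_equal(lam[34000], 0.9)       # baseline outside it
})

test_that("shared-source mixing plants inter-area theta coherence monotone in lambda", {
  beh <- test_behavior()
  n <- round(beh$duration * 1000)
  set.seed(21)
  shared <- jitter_phase_fixture(n)
  cvals <- sapply(c(0, 0.5, 0.9), function(lam) {
    ph <- phenotype_params(theta_amp = 4, delta_amp = 2, coherence_mix = lam)
    set.seed(10); x <- synthesize_lead_signal(ph, beh, shared_theta = shared)
    set.seed(20); y <- synthesize_lead_signal(ph, beh, shared_theta = shared)
    cs <- msc(x, y, 1000, max_freq = 100)
    mean(cs$c[cs$freqs >= 6 & cs$freqs <= 13])
  })
  expect_lt(cvals[1], 0.1)            # independent leads near the null floor
  expect_true(all(diff(cvals) > 0))   # monotone in the planted mixing weight
  expect_gt(cvals[3], 0.3)
})
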