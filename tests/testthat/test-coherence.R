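fs <- 1000

test_that("coherence is 1 for identical signals and near zero for independent noise", {
  set.seed(51)
  x <- rnorm(60 * fs)
  cs <- msc(x, x, fs)
  expect_equal(cs$c, rep(1, length(cs$c)), tolerance = 1e-9)

  # independent white noise with ~50 segments: small-sample bias only
  y <- rnorm(60 * fs)
  cs0 <- msc(x, y, fs, window_ms = 2000, overlap = 0.5)
  expect_lt(mean(cs0$c), 0.1)

  expect_error(msc(rnorm(1200), rnorm(1200), fs), "2 segments")
  expect_error(msc(rnorm(3000), rnorm(2000), fs), "lengths")
})

test_that("a shared 8 Hz source shows up at theta, not elsewhere, and msc is scale invariant", {
  set.seed(52)
  t <- (0:(120 * fs - 1)) / fs
  src <- sin(2 * pi * 8 * t + cumsum(rnorm(length(t), 0, 0.01)))
  x <- 0.7 * src + rnorm(length(t))
  y <- 0.7 * src + rnorm(length(t))
  cs <- msc(x, y, fs, max_freq = 100)
  expect_gt(cs$c[cs$freqs == 8], cs$c[cs$freqs == 30] + 0.3)

  cs2 <- msc(5 * x, 0.2 * y, fs, max_freq = 100)
  expect_equal(cs2$c, cs$c, tolerance = 1e-9)
  expect_true(all(cs$c >= 0 & cs$c <= 1))
})

test_that("per-trial theta coherence uses ipsilateral pairs and tracks identity", {
  s <- tiny_session()
  pairs <- ipsilateral_pairs(s$leads)
  expect_equal(nrow(pairs), 32)  # 4x4 pairs per hemisphere
  expect_true(all(s$leads$hemisphere[pairs$acc] == s$leads$hemisphere[pairs$hpc]))

  # copy one HPC signal onto every lead: coherence must be 1
  s2 <- s
  for (i in 2:16) s2$signals[i, ] <- s2$signals[1, ]
  tc <- session_trial_coherence(s2, notch = FALSE)
  expect_equal(tc$theta_coherence, rep(1, nrow(tc)), tolerance = 1e-6)
  expect_true(all(tc$truncated == (tc$delay_s < 10)))
})

test_that("difference scores follow their definition and the trial-count filter", {
  tc <- data.frame(
    session_id = rep(c("a", "b"), each = 8),
    theta_coherence = c(rep(0.5, 4), rep(0.6, 4), rep(0.4, 8)),
    outcome = rep(c("correct", "error"), 8),
    delay_category = rep(rep(c("short", "long"), each = 2), 4))
  # session a: error mean 0.55? construct explicit: correct rows get 0.5/0.6 alternating
  tc$theta_coherence <- ifelse(tc$session_id == "a",
                               ifelse(tc$outcome == "error", 0.6, 0.5), 0.4)
  ds <- difference_scores(tc)
  expect_equal(ds$scores$score[ds$scores$session_id == "a"], 1.2)
  expect_equal(ds$scores$score[ds$scores$session_id == "b"], 1.0)

  # equivariance: scaling all coherences leaves the score unchanged
  tc2 <- tc; tc2$theta_coherence <- tc2$theta_coherence * 0.37
  expect_equal(difference_scores(tc2)$scores$score, ds$scores$score)

  # split variant: session a has 2 trials per cell -> excluded at min 3
  dss <- difference_scores(tc, split_by_delay = TRUE, min_trials = 3)
  expect_setequal(dss$excluded, c("a", "b"))
  expect_equal(nrow(dss$scores) / 2 + length(dss$excluded), 2)

  dss2 <- difference_scores(tc, split_by_delay = TRUE, min_trials = 2)
  expect_equal(sort(unique(dss2$scores$session_id)), c("a", "b"))
  # retained + excluded = total sessions
  expect_equal(length(unique(dss2$scores$session_id)) + length(dss2$excluded), 2)
})

test_that("planted outcome-dependent coherence flips the difference score between presets", {
  tc <- effect_trial_coherence()
  ds <- difference_scores(tc)
  grp <- sapply(ds$scores$session_id, function(x) tc$group[tc$session_id == x][1])
  expect_lt(median(ds$scores$score[grp == "control"]), 1)
  expect_gt(median(ds$scores$score[grp == "STZ"]), 1)
})

test_that("the peri-event cohereogram localizes the delay-period coherence rise", {
  coh <- effect_cohort()
  stz <- coh[[which(sapply(coh, function(s) s$leads$group[1]) == "STZ")[1]]]
  pairs <- ipsilateral_pairs(stz$leads)
  pec <- peri_event_cohereogram(stz, pairs$acc[1], pairs$hpc[1], notch = FALSE)
  expect_equal(length(pec$t), 29)  # [-10, 4] s at 500 ms steps
  got <- pec$c[[which(pec$n_trials > 0)[1]]]
  expect_true(all(got >= 0 & got <= 1))
  # theta rows dominated by the shared source; line them up against 30+ Hz
  th <- pec$freqs >= 6 & pec$freqs <= 13
  hi <- pec$freqs >= 25 & pec$freqs <= 45
  expect_gt(mean(got[th, ]), mean(got[hi, ]) + 0.1)
})
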