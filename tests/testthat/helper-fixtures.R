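# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Scaled-down full-effect cohort: 2 subjects x 2 sessions per group,
# 14 trials per session, all planted effects at preset strength.
effect_cohort <- function() {
  fixture("effect_cohort", function() {
    generate_cohort(cohort_config(
      n_subjects = c(control = 2, STZ = 2),
      n_sessions_per_subject = 2, n_trials = 14, seed = 101))
  })
}

# Well-separated 4-class cohort with short sessions for decoding tests.
separable_cohort <- function() {
  fixture("separable_cohort", function() {
    generate_cohort(cohort_config(
      n_subjects = c(control = 3, STZ = 3),
      n_sessions_per_subject = 2, n_trials = 2,
      phenotypes = separable_phenotypes(), seed = 42))
  })
}

separable_dataset <- function() {
  fixture("separable_dataset", function() cohort_phenotype_dataset(separable_cohort()))
}

# One short behavior trace reused by signal-synthesis tests.
test_behavior <- function(n_trials = 6, seed = 301) {
  fixture(paste0("behavior_", n_trials, "_", seed), function() {
    set.seed(seed)
    generate_behavior(n_trials)
  })
}

# Tiny valid session built from constructed signals (no generator).
tiny_session <- function(n_trials = 2, seed = 11) {
  set.seed(seed)
  fs <- 1000
  dur <- 40
  leads <- standard_leads("subjA", "sesA", "control")
  sig <- matrix(rnorm(16 * dur * fs), nrow = 16)
  pos <- data.frame(t_s = seq(0.02, dur - 0.02, by = 0.04))
  pos$x_cm <- cumsum(rnorm(nrow(pos), 0, 0.1))
  pos$y_cm <- cumsum(rnorm(nrow(pos), 0, 0.1))
  ev <- data.frame(trial_index = seq_len(n_trials),
                   delay_start_s = c(2, 20)[seq_len(n_trials)],
                   trial_start_s = c(10, 28)[seq_len(n_trials)],
                   choice_time_s = c(13, 31)[seq_len(n_trials)],
                   return_time_s = c(18, 36)[seq_len(n_trials)],
                   outcome = c("correct", "error")[seq_len(n_trials)],
                   stringsAsFactors = FALSE)
  session_recording(sig, fs, leads, pos, ev)
}

# Shared theta source phase at 8 Hz for coherence-planting tests.
jitter_phase_fixture <- function(n) thetadyn:::jitter_phase(n, 8, 1000)

# Pooled per-trial theta coherence of the full-effect cohort.
effect_trial_coherence <- function() {
  fixture("effect_trial_coherence", function() {
    coh <- effect_cohort()
    rows <- lapply(names(coh), function(nm) {
      tc <- session_trial_coherence(coh[[nm]])
      tc$session_id <- nm
      tc$group <- coh[[nm]]$leads$group[1]
      tc
    })
    do.call(rbind, rows)
  })
}
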