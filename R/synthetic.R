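# Synthetic cohort generator: delayed-alternation behavior plus 16-lead
# LFP-like signals in which every analysed effect is planted with a named
# parameter (delta/theta balance, speed coupling, phase-amplitude
# coupling, shared-source inter-area coherence with outcome-dependent
# shifts, group-by-delay accuracy).

#' Phenotype parameters of one (group x area) signal generator
#'
#' The generative counterpart of the measured quantities: a 1/f
#' background plus delta and theta oscillators whose amplitudes couple to
#' running speed, theta-phase-modulated slow/fast gamma, and a shared
#' inter-area theta source mixed in with weight `coherence_mix`.
#'
#' @param delta_amp,theta_amp oscillator amplitudes (a.u., >= 0).
#' @param delta_freq,theta_freq center frequencies (Hz).
#' @param slow_gamma_amp,fast_gamma_amp gamma amplitudes (a.u.).
#' @param slow_gamma_freq,fast_gamma_freq gamma center frequencies (Hz).
#' @param pac_depth named vector of modulation depths kappa in [0,1] for
#'   `delta_theta`, `theta_slow_gamma`, `theta_fast_gamma`.
#' @param speed_coupling named vector: `delta` (beta <= 0) and `theta`
#'   (beta >= 0) amplitude gains per unit normalized speed.
#' @param coherence_mix lambda in [0,1], weight of the shared theta
#'   source relative to the lead's private theta oscillator.
#' @param coherence_outcome_shift signed lambda shift applied during
#'   error-trial delay windows (delay period plus the first 2 s of the
#'   run); the shifted lambda is clipped to [0,1].
#' @param coherence_long_multiplier multiplier on the shift for
#'   long-delay trials.
#' @param noise_exponent 1/f slope of the background (1 = pink).
#' @param noise_amp background standard deviation (a.u.).
#' @return list of class `phenotype_params`.
#' @export
phenotype_params <- function(delta_amp = 2, theta_amp = 4,
                             delta_freq = 2.5, theta_freq = 8,
                             slow_gamma_amp = 0.6, fast_gamma_amp = 0.4,
                             slow_gamma_freq = 40, fast_gamma_freq = 80,
                             pac_depth = c(delta_theta = 0,
                                           theta_slow_gamma = 0,
                                           theta_fast_gamma = 0),
                             speed_coupling = c(delta = 0, theta = 0),
                             coherence_mix = 0.5,
                             coherence_outcome_shift = 0,
                             coherence_long_multiplier = 1,
                             noise_exponent = 1, noise_amp = 2) {
  p <- list(delta_amp = delta_amp, theta_amp = theta_amp,
            delta_freq = delta_freq, theta_freq = theta_freq,
            slow_gamma_amp = slow_gamma_amp, fast_gamma_amp = fast_gamma_amp,
            slow_gamma_freq = slow_gamma_freq, fast_gamma_freq = fast_gamma_freq,
            pac_depth = pac_depth, speed_coupling = speed_coupling,
            coherence_mix = coherence_mix,
            coherence_outcome_shift = coherence_outcome_shift,
            coherence_long_multiplier = coherence_long_multiplier,
            noise_exponent = noise_exponent, noise_amp = noise_amp)
  if (any(c(p$delta_amp, p$theta_amp, p$slow_gamma_amp, p$fast_gamma_amp,
            p$noise_amp) < 0)) {
    stop("parameter error: amplitudes must be >= 0", call. = FALSE)
  }
  if (any(p$pac_depth < 0 | p$pac_depth > 1)) {
    stop("parameter error: pac_depth kappa must lie in [0,1]", call. = FALSE)
  }
  if (p$coherence_mix < 0 || p$coherence_mix > 1) {
    stop("parameter error: coherence_mix lambda must lie in [0,1]", call. = FALSE)
  }
  if (p$speed_coupling[["delta"]] > 0 || p$speed_coupling[["theta"]] < 0) {
    stop("parameter error: speed_coupling requires delta <= 0 and theta >= 0", call. = FALSE)
  }
  class(p) <- "phenotype_params"
  p
}

#' Built-in phenotype preset sets
#'
#' `default_phenotypes()` plants the qualitative effect pattern the
#' pipeline is designed to detect: the control hippocampus is theta
#' dominated and the STZ-like hippocampus delta dominated; cross-
#' frequency coupling is elevated in the STZ-like phenotype; the shared
#' theta mixing weight drops on control error trials and rises (more so
#' on long delays) on STZ-like error trials. All numbers are package
#' defaults describing the planted direction of each effect, not
#' measured values.
#'
#' `separable_phenotypes()` is a clean four-class set with distinct
#' spectral peaks and a weak background, used as the decoding oracle.
#'
#' @return named list of [phenotype_params()] keyed `"group.area"`.
#' @export
default_phenotypes <- function() {
  list(
    control.HPC = phenotype_params(
      delta_amp = 2, theta_amp = 6,
      pac_depth = c(delta_theta = 0.10, theta_slow_gamma = 0.20, theta_fast_gamma = 0.15),
      speed_coupling = c(delta = -0.5, theta = 0.8),
      coherence_mix = 0.6, coherence_outcome_shift = -0.25),
    control.ACC = phenotype_params(
      delta_amp = 2.5, theta_amp = 3,
      pac_depth = c(delta_theta = 0.08, theta_slow_gamma = 0.15, theta_fast_gamma = 0.10),
      speed_coupling = c(delta = -0.5, theta = 0.8),
      coherence_mix = 0.6, coherence_outcome_shift = -0.25),
    STZ.HPC = phenotype_params(
      delta_amp = 4.5, theta_amp = 3.5,
      pac_depth = c(delta_theta = 0.40, theta_slow_gamma = 0.50, theta_fast_gamma = 0.35),
      speed_coupling = c(delta = -0.5, theta = 0.8),
      coherence_mix = 0.75, coherence_outcome_shift = 0.15,
      coherence_long_multiplier = 1.5),
    STZ.ACC = phenotype_params(
      delta_amp = 4, theta_amp = 2,
      pac_depth = c(delta_theta = 0.15, theta_slow_gamma = 0.35, theta_fast_gamma = 0.12),
      speed_coupling = c(delta = -0.5, theta = 0.8),
      coherence_mix = 0.75, coherence_outcome_shift = 0.15,
      coherence_long_multiplier = 1.5)
  )
}

#' @rdname default_phenotypes
#' @export
separable_phenotypes <- function() {
  list(
    control.HPC = phenotype_params(delta_amp = 1, theta_amp = 8, theta_freq = 11,
                                   noise_amp = 0.5),
    control.ACC = phenotype_params(delta_amp = 1, theta_amp = 8, theta_freq = 7,
                                   noise_amp = 0.5),
    STZ.HPC = phenotype_params(delta_amp = 6, theta_amp = 2, delta_freq = 3.5,
                               theta_freq = 11, noise_amp = 0.5),
    STZ.ACC = phenotype_params(delta_amp = 6, theta_amp = 2, delta_freq = 2,
                               theta_freq = 7, noise_amp = 0.5)
  )
}

#' Cohort configuration
#'
#' The seed fully determines the cohort; every (session, hemisphere,
#' lead) draws from its own named stream derived from it, so enlarging
#' the cohort never perturbs existing sessions.
#'
#' @param n_subjects named vector: subjects per group.
#' @param n_sessions_per_subject sessions per subject (scalar or named
#'   per group).
#' @param n_trials delayed-alternation trials per session; delays are
#'   uniform on [5, 45] s.
#' @param accuracy list per group of `c(short = p, long = p)` success
#'   probabilities.
#' @param phenotypes named list of [phenotype_params()] keyed
#'   `"group.area"`.
#' @param shared_theta_freq Hz of the shared inter-area theta source.
#' @param sample_rate LFP sampling rate (Hz).
#' @param pos_rate position tracking rate (Hz).
#' @param seed master seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = c(control = 3, STZ = 5),
                          n_sessions_per_subject = c(control = 5, STZ = 4),
                          n_trials = 30,
                          accuracy = list(control = c(short = 0.90, long = 0.85),
                                          STZ = c(short = 0.85, long = 0.60)),
                          phenotypes = default_phenotypes(),
                          shared_theta_freq = 8,
                          sample_rate = 1000, pos_rate = 25, seed = 1) {
  if (n_trials <= 0) stop("config error: n_trials must be positive", call. = FALSE)
  for (g in names(accuracy)) {
    if (any(accuracy[[g]] < 0 | accuracy[[g]] > 1)) {
      stop("config error: accuracy probabilities must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects,
                 n_sessions_per_subject = n_sessions_per_subject,
                 n_trials = n_trials, accuracy = accuracy,
                 phenotypes = phenotypes,
                 shared_theta_freq = shared_theta_freq,
                 sample_rate = sample_rate, pos_rate = pos_rate,
                 seed = seed),
            class = "cohort_config")
}

# Smooth unit ramp: s(0)=0, s(1)=1, zero end-point speed.
smooth_ramp <- function(u) u - sin(2 * pi * u) / (2 * pi)

# Map arc length along the canonical loop (stem up, arm out, arm down,
# return) to coordinates; `side` = +/-1 selects the mirrored circuit.
arc_to_xy <- function(arc, side) {
  stem <- 74; arm <- 63.5
  l1 <- stem; l2 <- l1 + arm; l3 <- l2 + stem; l4 <- l3 + arm
  x <- y <- numeric(length(arc))
  a <- arc
  i <- a <= l1
  x[i] <- 0; y[i] <- a[i]
  i <- a > l1 & a <= l2
  x[i] <- a[i] - l1; y[i] <- stem
  i <- a > l2 & a <= l3
  x[i] <- arm; y[i] <- stem - (a[i] - l2)
  i <- a > l3
  x[i] <- arm - (a[i] - l3); y[i] <- 0
  cbind(x_cm = x * side, y_cm = y)
}

#' Generate delayed-alternation behavior for one session
#'
#' Delays are i.i.d. uniform on [5, 45] s; outcomes are Bernoulli with
#' the category-specific success probability; positions trace the T-maze
#' circuit (alternating arms) with stationary delay epochs and smooth
#' run/return epochs whose speed profile does not depend on group or
#' outcome. Draws from the current RNG state.
#'
#' @param n_trials number of trials (> 0).
#' @param p_correct `c(short = p, long = p)`.
#' @param pos_rate tracking rate (Hz).
#' @return list with `positions`, `events`, `duration` (s).
#' @export
generate_behavior <- function(n_trials, p_correct = c(short = 0.9, long = 0.8),
                              pos_rate = 25) {
  if (n_trials <= 0) stop("config error: n_trials must be positive", call. = FALSE)
  half_loop <- 74 + 63.5
  delay_s <- runif(n_trials, 5, 45)
  run_dur <- 5.5 + runif(n_trials, -0.5, 0.5)
  ret_dur <- 6.0 + runif(n_trials, -0.5, 0.5)
  cat <- ifelse(delay_s < DELAY_SPLIT_S, "short", "long")
  outcome <- ifelse(runif(n_trials) < p_correct[cat], "correct", "error")

  delay_start <- trial_start <- choice_time <- return_time <- numeric(n_trials)
  t0 <- 2
  for (i in seq_len(n_trials)) {
    delay_start[i] <- t0
    trial_start[i] <- delay_start[i] + delay_s[i]
    choice_time[i] <- trial_start[i] + run_dur[i]
    return_time[i] <- choice_time[i] + ret_dur[i]
    t0 <- return_time[i]
  }
  duration <- return_time[n_trials] + 2

  t <- seq(0, duration, by = 1 / pos_rate)
  arc <- numeric(length(t))
  side <- rep(1, length(t))
  for (i in seq_len(n_trials)) {
    s_i <- if (i %% 2 == 0) -1 else 1
    run <- t >= trial_start[i] & t < choice_time[i]
    arc[run] <- half_loop * smooth_ramp((t[run] - trial_start[i]) / run_dur[i])
    side[run] <- s_i
    ret <- t >= choice_time[i] & t < return_time[i]
    arc[ret] <- half_loop * (1 + smooth_ramp((t[ret] - choice_time[i]) / ret_dur[i]))
    side[ret] <- s_i
  }
  xy <- arc_to_xy(arc, side)
  jit <- matrix(rnorm(2 * length(t), 0, 0.02), ncol = 2)
  positions <- data.frame(t_s = t,
                          x_cm = xy[, 1] + jit[, 1],
                          y_cm = xy[, 2] + jit[, 2])
  events <- data.frame(trial_index = seq_len(n_trials),
                       delay_start_s = delay_start, trial_start_s = trial_start,
                       choice_time_s = choice_time, return_time_s = return_time,
                       outcome = outcome, stringsAsFactors = FALSE)
  list(positions = positions, events = events, duration = duration)
}

# 1/f^alpha background via spectral shaping of white noise, unit sd.
pink_noise <- function(n, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  nfft <- stats::nextn(n, c(2, 3, 5))  # pad to an FFT-friendly length
  W <- fft(c(w, rep(0, nfft - n)))
  k <- seq_len(nfft) - 1
  f <- pmin(k, nfft - k)       # symmetric frequency index
  sc <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(W * sc, inverse = TRUE))[seq_len(n)] / nfft
  x / sd(x)
}

# Jittered oscillator phase: integrated instantaneous frequency with
# fast jitter (SD `jitter_sd` Hz, 10 Hz knots, widens the band) plus a
# slow frequency drift (SD `drift_sd` Hz, 0.2 Hz knots) that makes
# independent oscillators decohere on the seconds timescale, and a
# random start phase. Without the slow drift, fast jitter integrates
# away and two independent oscillators stay spuriously phase-locked
# over trial-length windows.
jitter_phase <- function(n, f0, sample_rate, jitter_sd = 0.1, drift_sd = 0.3) {
  grid01 <- seq(0, 1, length.out = n)
  n_fast <- max(2L, ceiling(n / sample_rate * 10) + 1L)
  fast <- approx(seq(0, 1, length.out = n_fast), rnorm(n_fast, 0, jitter_sd),
                 xout = grid01)$y
  n_slow <- max(2L, ceiling(n / sample_rate * 0.2) + 1L)
  slow <- approx(seq(0, 1, length.out = n_slow), rnorm(n_slow, 0, drift_sd),
                 xout = grid01)$y
  cumsum(2 * pi * (f0 + fast + slow) / sample_rate) + runif(1, 0, 2 * pi)
}

#' Per-sample shared-theta mixing weight for one lead
#'
#' Starts from the phenotype's baseline lambda and applies the signed
#' outcome shift during each error trial's delay window (delay period
#' plus the first 2 s of the run), scaled by the long-delay multiplier
#' for long trials, then clips to [0,1].
#'
#' @param phen a [phenotype_params()].
#' @param events event data.frame.
#' @param n_samples,sample_rate signal geometry.
#' @return numeric vector of length `n_samples`.
#' @export
lambda_series <- function(phen, events, n_samples, sample_rate) {
  lam <- rep(phen$coherence_mix, n_samples)
  if (nrow(events) == 0 || phen$coherence_outcome_shift == 0) return(clip01(lam))
  tt <- build_trial_table(events)
  err <- which(tt$outcome == "error")
  for (i in err) {
    mult <- if (tt$delay_category[i] == "long") phen$coherence_long_multiplier else 1
    i0 <- max(1L, round(tt$delay_start_s[i] * sample_rate) + 1L)
    i1 <- min(n_samples, round((tt$trial_start_s[i] + 2) * sample_rate))
    lam[i0:i1] <- lam[i0:i1] + phen$coherence_outcome_shift * mult
  }
  clip01(lam)
}

#' Synthesize one lead's signal
#'
#' signal = 1/f background
#'   + a_delta(t) cos(phi_delta) with a_delta = delta_amp * max(0, 1 + beta_delta * v)
#'   + a_theta(t) * [lambda(t) cos(phi_shared) + (1 - lambda(t)) cos(phi_private)]
#'     with a_theta = theta_amp * (1 + beta_theta * v) * (1 + kappa_dt cos(phi_delta))
#'   + sum over gammas of A_g [1 + kappa_g cos(phi_theta_carrier)] cos(phi_g)
#'
#' where v is running speed normalized to [0,1] and phi_theta_carrier is
#' the phase of the mixed theta component. Draws from the current RNG
#' state; callers seed a named stream per lead.
#'
#' @param phen a [phenotype_params()].
#' @param behavior output of [generate_behavior()].
#' @param sample_rate Hz.
#' @param shared_theta optional phase vector of the shared theta source
#'   (length = n_samples); when NULL the lead is fully private.
#' @param lam optional per-sample mixing weight (defaults to
#'   [lambda_series()] of the phenotype and the behavior's events).
#' @return numeric signal of length `round(duration * sample_rate)`.
#' @export
synthesize_lead_signal <- function(phen, behavior, sample_rate = 1000,
                                   shared_theta = NULL, lam = NULL) {
  n <- round(behavior$duration * sample_rate)
  tgrid <- (seq_len(n) - 1) / sample_rate

  sp <- running_speed(behavior$positions)
  v <- interp_series(sp$t_s, sp$speed_cm_s, tgrid)
  vtop <- as.numeric(quantile(v, 0.95))
  vhat <- if (vtop > 0) clip01(v / vtop) else rep(0, n)

  x <- phen$noise_amp * pink_noise(n, phen$noise_exponent)

  phi_d <- jitter_phase(n, phen$delta_freq, sample_rate)
  beta_d <- phen$speed_coupling[["delta"]]
  a_d <- phen$delta_amp * pmax(0, 1 + beta_d * vhat)
  x <- x + a_d * cos(phi_d)

  phi_p <- jitter_phase(n, phen$theta_freq, sample_rate)
  beta_t <- phen$speed_coupling[["theta"]]
  kdt <- phen$pac_depth[["delta_theta"]]
  a_t <- phen$theta_amp * (1 + beta_t * vhat) * (1 + kdt * cos(phi_d))
  a_t <- pmax(0, a_t)
  if (is.null(shared_theta)) {
    theta_osc <- cos(phi_p)
    phi_carrier <- phi_p
  } else {
    if (length(shared_theta) != n) {
      stop("parameter error: shared_theta length must match the signal", call. = FALSE)
    }
    if (is.null(lam)) lam <- lambda_series(phen, behavior$events, n, sample_rate)
    theta_osc <- lam * cos(shared_theta) + (1 - lam) * cos(phi_p)
    phi_carrier <- atan2(lam * sin(shared_theta) + (1 - lam) * sin(phi_p),
                         lam * cos(shared_theta) + (1 - lam) * cos(phi_p))
  }
  x <- x + a_t * theta_osc

  for (g in c("slow_gamma", "fast_gamma")) {
    amp <- phen[[paste0(g, "_amp")]]
    if (amp <= 0) next
    kap <- phen$pac_depth[[paste0("theta_", g)]]
    phi_g <- jitter_phase(n, phen[[paste0(g, "_freq")]], sample_rate, jitter_sd = 0.5)
    x <- x + amp * (1 + kap * cos(phi_carrier)) * cos(phi_g)
  }
  x
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the config's seed. Each session carries 16 leads
#' (4 per area per hemisphere); within a hemisphere the ACC and HPC
#' leads mix in one shared theta source, planting inter-area coherence.
#'
#' @param config a [cohort_config()].
#' @return named list of `session_recording` keyed by session_id.
#' @export
generate_cohort <- function(config) {
  sessions <- list()
  for (g in names(config$n_subjects)) {
    nspg <- config$n_sessions_per_subject
    n_sess <- if (length(nspg) > 1) nspg[[g]] else nspg
    for (subj in seq_len(config$n_subjects[[g]])) {
      subject_id <- sprintf("%s%02d", g, subj)
      for (sess in seq_len(n_sess)) {
        session_id <- sprintf("%s_S%d", subject_id, sess)
        sessions[[session_id]] <- generate_session(config, g, subj, sess,
                                                   subject_id, session_id)
      }
    }
  }
  sessions
}

generate_session <- function(config, group, subj, sess, subject_id, session_id) {
  fs <- config$sample_rate
  set.seed(stream_seed(config$seed, group, subj, sess, "behavior"))
  beh <- generate_behavior(config$n_trials, config$accuracy[[group]],
                           config$pos_rate)
  n <- round(beh$duration * fs)
  shared <- list()
  for (h in HEMISPHERES) {
    set.seed(stream_seed(config$seed, group, subj, sess, h, "shared_theta"))
    shared[[h]] <- jitter_phase(n, config$shared_theta_freq, fs)
  }
  leads <- standard_leads(subject_id, session_id, group)
  signals <- matrix(0, nrow(leads), n)
  for (i in seq_len(nrow(leads))) {
    phen <- config$phenotypes[[paste(group, leads$area[i], sep = ".")]]
    if (is.null(phen)) stop("config error: no phenotype for ", group, ".", leads$area[i], call. = FALSE)
    set.seed(stream_seed(config$seed, group, subj, sess, leads$lead_id[i]))
    signals[i, ] <- synthesize_lead_signal(phen, beh, fs,
                                           shared_theta = shared[[leads$hemisphere[i]]])
  }
  session_recording(signals, fs, leads, beh$positions, beh$events)
}

#' Write a cohort of sessions under one directory
#' @param cohort named list from [generate_cohort()].
#' @param path target directory (one subdirectory per session).
#' @export
write_cohort <- function(cohort, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (sid in names(cohort)) write_session(cohort[[sid]], file.path(path, sid))
  invisible(path)
}

#' Read every session directory under a cohort directory
#' @param path cohort directory.
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "signals.json"))]
  out <- lapply(dirs, read_session)
  names(out) <- basename(dirs)
  out
}
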