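# Group-comparison statistics (first-principles Kruskal-Wallis and
# running one-way F), band-power/speed coupling, and the full pipeline
# orchestrator.

#' Pearson correlation between a band-power series and running speed
#'
#' Speed is interpolated linearly onto the spectrogram frame times.
#'
#' @param band_series per-frame band power (from [band_power()]).
#' @param frame_times frame centers (s).
#' @param speed data.frame from [running_speed()].
#' @return Pearson r.
#' @export
speed_power_correlation <- function(band_series, frame_times, speed) {
  if (length(band_series) < 10) stop("parameter error: need >= 10 paired samples", call. = FALSE)
  v <- interp_series(speed$t_s, speed$speed_cm_s, frame_times)
  if (sd(band_series) == 0 || sd(v) == 0) {
    stop("undefined-r error: zero-variance series", call. = FALSE)
  }
  cor(band_series, v)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H with tie correction and the chi-square approximation on
#' k - 1 degrees of freedom, computed from the textbook formula.
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 1
#'   observation).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(!vapply(groups, length, 1L))) {
    stop("parameter error: need >= 2 non-empty groups", call. = FALSE)
  }
  x <- unlist(groups)
  n <- length(x)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  df <- length(groups) - 1
  list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE))
}

#' Per-trial peri-event theta/delta ratio matrix
#'
#' For every trial whose window fits inside the session, each of the
#' area's leads is decomposed around trial start with a dedicated
#' 1000 ms window / 500 ms hop spectrogram; the per-frame TD ratio is
#' averaged over leads, giving one row per trial at 500 ms steps.
#'
#' @param session a `session_recording`.
#' @param area which area's leads to average ("HPC" or "ACC").
#' @param window c(before, after) in s around trial start.
#' @param step_ms step between frames (default 500).
#' @param notch apply the 60 Hz notch first.
#' @return list: `t` (s rel. trial start), `td` [n_trials x n_steps],
#'   `outcome`, `delay_category`.
#' @export
peri_event_td <- function(session, area = "HPC", window = c(-10, 4),
                          step_ms = 500, notch = TRUE) {
  fs <- session$sample_rate
  idx <- which(session$leads$area == area)
  sig <- session$signals[idx, , drop = FALSE]
  if (notch) for (i in seq_len(nrow(sig))) sig[i, ] <- notch_60hz(sig[i, ], fs)
  n <- ncol(sig)
  win_ms <- 1000
  centers <- seq(window[1], window[2], by = step_ms / 1000)
  tt <- build_trial_table(session$events)
  theta <- band_def("theta"); delta <- band_def("delta")
  rows <- list(); keep_tr <- integer()
  for (r in seq_len(nrow(tt))) {
    t0 <- tt$trial_start_s[r]
    i0 <- round((t0 + window[1] - win_ms / 2000) * fs) + 1L
    i1 <- round((t0 + window[2] + win_ms / 2000) * fs)
    if (i0 < 1 || i1 > n) next
    td_leads <- matrix(0, length(idx), length(centers))
    for (k in seq_len(nrow(sig))) {
      fr <- compute_spectrogram(sig[k, i0:i1], fs, window_ms = win_ms,
                                overlap_ms = win_ms - step_ms)
      td_leads[k, ] <- td_ratio(band_power(fr, theta),
                                band_power(fr, delta))[seq_along(centers)]
    }
    rows[[length(rows) + 1L]] <- colMeans(td_leads)
    keep_tr <- c(keep_tr, r)
  }
  list(t = centers,
       td = if (length(rows)) do.call(rbind, rows) else matrix(0, 0, length(centers)),
       outcome = tt$outcome[keep_tr],
       delay_category = tt$delay_category[keep_tr])
}

#' Running one-way F test between groups at each peri-event step
#'
#' Classical equal-variance one-way ANOVA F at each 500 ms step, with a
#' Bonferroni-corrected significance mask over the steps.
#'
#' @param td_by_group named list of two matrices [trials x steps] on a
#'   common step grid (e.g. stacked [peri_event_td()] outputs per
#'   group).
#' @param t step times (s).
#' @param alpha familywise level before Bonferroni correction.
#' @return data.frame: t, F, df1, df2, p, significant (p < alpha /
#'   n_steps); steps with fewer than 2 trials in a group are skipped
#'   (NA).
#' @export
running_group_F <- function(td_by_group, t, alpha = 0.05) {
  k <- length(td_by_group)
  n_steps <- length(t)
  out <- data.frame(t = t, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_, significant = FALSE)
  for (s in seq_len(n_steps)) {
    vals <- lapply(td_by_group, function(m) m[is.finite(m[, s]), s])
    if (any(vapply(vals, length, 1L) < 2)) next
    x <- unlist(vals)
    g <- rep(seq_len(k), vapply(vals, length, 1L))
    grand <- mean(x)
    ssb <- sum(vapply(vals, function(v) length(v) * (mean(v) - grand)^2, 1))
    ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 1))
    df1 <- k - 1; df2 <- length(x) - k
    f <- (ssb / df1) / (ssw / df2)
    out$F[s] <- f; out$df1[s] <- df1; out$df2[s] <- df2
    out$p[s] <- pf(f, df1, df2, lower.tail = FALSE)
  }
  out$significant <- !is.na(out$p) & out$p < alpha / sum(!is.na(out$p))
  out
}

#' Run the full analysis pipeline over a cohort
#'
#' Executes every stage in order — spectral profiles and TD ratios,
#' behavior summaries, speed-power coupling, phase-amplitude coupling,
#' per-trial coherence with difference scores, phenotype decoding, and
#' the group statistics — and returns the result tables (optionally
#' written as CSV under `out_dir`). Deterministic given `seed`.
#'
#' @param cohort named list of `session_recording`.
#' @param seed seed for the decoding resampling protocols.
#' @param decode_sizes training sizes for the sweep.
#' @param n_iter iterations for sweep/null protocols.
#' @param run_pac,run_peri toggle the costlier stages.
#' @param out_dir optional directory for CSV export.
#' @return named list of tables (see details in the vignette).
#' @export
run_full_analysis <- function(cohort, seed = 1,
                              decode_sizes = c(5, 15, 25, 40), n_iter = 100,
                              run_pac = TRUE, run_peri = TRUE,
                              out_dir = NULL) {
  theta <- band_def("theta"); delta <- band_def("delta")
  lead_rows <- list(); spectra <- list(); trial_rows <- list()
  pac_rows <- list(); coh_rows <- list(); peri_by_group <- list()
  peri_t <- NULL

  for (sid in names(cohort)) {
    ses <- cohort[[sid]]
    fs <- ses$sample_rate
    grp <- ses$leads$group[1]
    speed <- running_speed(ses$positions)

    for (i in seq_len(nrow(ses$leads))) {
      x <- notch_60hz(ses$signals[i, ], fs)
      fr <- compute_spectrogram(x, fs)
      spec <- session_psd(fr, c(1, 100), lead_id = ses$leads$lead_id[i])
      spectra[[spec$lead_id]] <- spec
      th_series <- band_power(fr, theta)
      de_series <- band_power(fr, delta)
      lead_rows[[spec$lead_id]] <- data.frame(
        session_id = sid, lead_id = spec$lead_id,
        subject_id = ses$leads$subject_id[i],
        area = ses$leads$area[i], group = grp,
        delta_power = band_power(spec, delta),
        theta_power = band_power(spec, theta),
        td_ratio = td_ratio(mean(th_series), mean(de_series)),
        r_speed_theta = speed_power_correlation(th_series, fr$frame_times, speed),
        r_speed_delta = speed_power_correlation(de_series, fr$frame_times, speed),
        r_speed_td = speed_power_correlation(
          td_ratio(th_series, de_series), fr$frame_times, speed),
        stringsAsFactors = FALSE)
    }

    tt <- build_trial_table(ses$events)
    tt$session_id <- sid; tt$group <- grp
    trial_rows[[sid]] <- tt

    tc <- session_trial_coherence(ses)
    tc$session_id <- sid; tc$group <- grp
    coh_rows[[sid]] <- tc

    if (run_pac) {
      pac <- session_pac_summary(ses)
      pac$session_id <- sid; pac$group <- grp
      pac_rows[[sid]] <- pac
    }
    if (run_peri) {
      pe <- peri_event_td(ses, area = "HPC")
      peri_t <- pe$t
      peri_by_group[[grp]] <- rbind(peri_by_group[[grp]], pe$td)
    }
  }

  leads_tab <- do.call(rbind, c(lead_rows, list(make.row.names = FALSE)))
  trials_tab <- do.call(rbind, c(trial_rows, list(make.row.names = FALSE)))
  coh_tab <- do.call(rbind, c(coh_rows, list(make.row.names = FALSE)))
  pac_tab <- if (run_pac) do.call(rbind, c(pac_rows, list(make.row.names = FALSE))) else NULL

  session_td <- stats::aggregate(td_ratio ~ session_id + area + group,
                                 data = leads_tab, FUN = mean)
  accuracy <- accuracy_by_delay(trials_tab)
  dscores <- difference_scores(coh_tab)
  dscores_split <- difference_scores(coh_tab, split_by_delay = TRUE)

  # group comparisons: session TD ratios (per area) and, when present,
  # session MI per (area, pair)
  kw_rows <- list()
  for (a in unique(session_td$area)) {
    sub <- session_td[session_td$area == a, ]
    if (length(unique(sub$group)) == 2) {
      kw <- kruskal_wallis(split(sub$td_ratio, sub$group))
      kw_rows[[paste0("td_", a)]] <- data.frame(
        measure = paste0("td_ratio_", a), H = kw$H, df = kw$df, p = kw$p)
    }
  }
  if (!is.null(pac_tab)) {
    for (a in unique(pac_tab$area)) for (pr in unique(pac_tab$pair)) {
      sub <- pac_tab[pac_tab$area == a & pac_tab$pair == pr, ]
      if (length(unique(sub$group)) == 2) {
        kw <- kruskal_wallis(split(sub$mi, sub$group))
        kw_rows[[paste(a, pr)]] <- data.frame(
          measure = paste("mi", a, pr, sep = "_"), H = kw$H, df = kw$df, p = kw$p)
      }
    }
  }
  kw_tab <- if (length(kw_rows)) do.call(rbind, c(kw_rows, list(make.row.names = FALSE))) else NULL

  running_F <- if (run_peri && length(peri_by_group) == 2) {
    running_group_F(peri_by_group, peri_t)
  } else NULL

  decoding <- NULL
  if (length(unique(leads_tab$group)) == 2 && length(unique(leads_tab$area)) == 2) {
    all_leads <- do.call(rbind, lapply(cohort, function(s) s$leads))
    ds <- build_phenotype_dataset(spectra[all_leads$lead_id], all_leads)
    min_class <- min(table(ds$labels))
    sizes <- decode_sizes[decode_sizes < min_class]
    if (length(sizes)) {
      sweep <- training_size_sweep(ds, sizes, n_iter = n_iter, seed = seed,
                                   posterior = FALSE)
      null <- shuffled_null(ds, size = max(sizes), n_iter = n_iter, seed = seed)
      decoding <- list(
        sweep = data.frame(size = sizes,
                           mean_accuracy = vapply(sweep, function(s) mean(s$accuracy), 1),
                           sd_accuracy = vapply(sweep, function(s) sd(s$accuracy), 1)),
        null_mean = null$mean, null_ci95 = null$ci95,
        null_misclass = null$misclass, detail = sweep)
    }
  } else {
    message("decoding stage skipped: cohort lacks both groups or both areas")
  }

  report <- list(leads = leads_tab, session_td = session_td,
                 trials = trials_tab, accuracy = accuracy,
                 pac = pac_tab, trial_coherence = coh_tab,
                 difference_scores = dscores,
                 difference_scores_by_delay = dscores_split,
                 kruskal = kw_tab, running_F = running_F,
                 decoding = decoding,
                 manifest = list(seed = seed, decode_sizes = decode_sizes,
                                 n_iter = n_iter,
                                 n_sessions = length(cohort)))
  if (!is.null(out_dir)) export_report(report, out_dir)
  report
}

#' Write a report bundle's tables as CSV
#' @param report from [run_full_analysis()].
#' @param out_dir target directory.
#' @export
export_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                                row.names = FALSE)
  }
  wr(report$leads, "leads")
  wr(report$session_td, "session_td")
  wr(report$trials, "trials")
  wr(report$accuracy, "accuracy")
  wr(report$pac, "pac")
  wr(report$trial_coherence, "trial_coherence")
  wr(report$difference_scores$scores, "difference_scores")
  wr(report$difference_scores_by_delay$scores, "difference_scores_by_delay")
  wr(report$kruskal, "kruskal")
  wr(report$running_F, "running_F")
  if (!is.null(report$decoding)) wr(report$decoding$sweep, "decoding_sweep")
  writeLines(jsonlite::toJSON(report$manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
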