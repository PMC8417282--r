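# Inter-area magnitude-squared coherence: Welch estimator, peri-event
# cohereograms, per-trial delay-period theta coherence and error/correct
# difference scores.

# Hamming-tapered segment FFTs for Welch cross/auto spectra.
welch_segments <- function(x, nwin, hop) {
  n_seg <- floor((length(x) - nwin) / hop) + 1L
  w <- signal::hamming(nwin)
  n_freq <- nwin %/% 2 + 1L
  out <- matrix(0 + 0i, n_freq, n_seg)
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1L) * hop + 1L):((k - 1L) * hop + nwin)]
    out[, k] <- fft((seg - mean(seg)) * w)[seq_len(n_freq)]
  }
  out
}

#' Magnitude-squared coherence of two signals
#'
#' Welch-averaged cross and auto spectra combined as
#' C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f)), which lies in [0, 1].
#' Requires at least two segments (a single segment gives the degenerate
#' estimate C = 1 everywhere).
#'
#' @param x,y equal-length signals.
#' @param sample_rate Hz.
#' @param window_ms segment length (default 1000 ms, 1 Hz resolution at
#'   1 kHz).
#' @param overlap segment overlap fraction (default 0.5).
#' @param max_freq truncate the returned spectrum (Hz).
#' @return list with `freqs` and `c` in [0, 1].
#' @export
msc <- function(x, y, sample_rate, window_ms = 1000, overlap = 0.5,
                max_freq = sample_rate / 2) {
  if (length(x) != length(y)) stop("parameter error: unequal signal lengths", call. = FALSE)
  nwin <- round(window_ms * sample_rate / 1000)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n_seg <- floor((length(x) - nwin) / hop) + 1L
  if (n_seg < 2) {
    stop("degenerate-estimate error: need >= 2 segments (coherence of one segment is 1)",
         call. = FALSE)
  }
  X <- welch_segments(x, nwin, hop)
  Y <- welch_segments(y, nwin, hop)
  pxy <- rowMeans(X * Conj(Y))
  pxx <- rowMeans(Mod(X)^2)
  pyy <- rowMeans(Mod(Y)^2)
  cxy <- Mod(pxy)^2 / (pxx * pyy)
  freqs <- (seq_len(nrow(X)) - 1L) * sample_rate / nwin
  keep <- freqs <= max_freq
  list(freqs = freqs[keep], c = pmin(1, as.numeric(cxy[keep])))
}

#' All ipsilateral ACC x HPC lead pairs of a session
#'
#' @param leads a session's leads table.
#' @return data.frame with `acc` and `hpc` row indices and `hemisphere`.
#' @export
ipsilateral_pairs <- function(leads) {
  out <- list()
  for (h in unique(leads$hemisphere)) {
    acc <- which(leads$area == "ACC" & leads$hemisphere == h)
    hpc <- which(leads$area == "HPC" & leads$hemisphere == h)
    if (length(acc) && length(hpc)) {
      out[[h]] <- data.frame(expand.grid(acc = acc, hpc = hpc), hemisphere = h)
    }
  }
  if (!length(out)) stop("configuration error: no ipsilateral ACC x HPC pairs", call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-trial delay-period theta coherence
#'
#' For each trial the analysis window is the last 10 s of the delay
#' period plus the first 2 s of the trial run (shorter delays use the
#' full available delay and are flagged). Magnitude-squared coherence is
#' estimated on that window for every ipsilateral ACC x HPC pair
#' (1000 ms segments, 50% overlap), averaged over the theta band, then
#' over pairs: one value per trial.
#'
#' @param session a `session_recording`.
#' @param theta theta band (default 6-13 Hz).
#' @param notch apply the 60 Hz notch first.
#' @return data.frame: trial_index, theta_coherence, outcome,
#'   delay_category, delay_s, truncated.
#' @export
session_trial_coherence <- function(session, theta = band_def("theta"),
                                    notch = TRUE) {
  fs <- session$sample_rate
  tt <- build_trial_table(session$events)
  pairs <- ipsilateral_pairs(session$leads)
  sig <- session$signals
  if (notch) {
    used <- sort(unique(c(pairs$acc, pairs$hpc)))
    for (i in used) sig[i, ] <- notch_60hz(sig[i, ], fs)
  }
  n <- ncol(sig)
  out <- tt[, c("trial_index", "outcome", "delay_category", "delay_s")]
  out$theta_coherence <- NA_real_
  out$truncated <- FALSE
  for (r in seq_len(nrow(tt))) {
    w0 <- max(tt$delay_start_s[r], tt$trial_start_s[r] - 10)
    w1 <- tt$trial_start_s[r] + 2
    out$truncated[r] <- tt$delay_s[r] < 10
    i0 <- max(1L, round(w0 * fs) + 1L)
    i1 <- min(n, round(w1 * fs))
    vals <- numeric(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      cs <- msc(sig[pairs$acc[p], i0:i1], sig[pairs$hpc[p], i0:i1], fs,
                max_freq = 100)
      sel <- cs$freqs >= theta$lo & cs$freqs <= theta$hi
      vals[p] <- mean(cs$c[sel])
    }
    out$theta_coherence[r] <- mean(vals)
  }
  out[, c("trial_index", "theta_coherence", "outcome", "delay_category",
          "delay_s", "truncated")]
}

#' Error/correct coherence difference scores per session
#'
#' score = mean(error-trial theta coherence) / mean(correct-trial theta
#' coherence). The delay-split variant computes the score separately for
#' short and long trials and keeps only sessions with at least
#' `min_trials` (default 3) trials in each of the four
#' (outcome x delay) cells; excluded sessions are reported.
#'
#' @param trial_coherence data.frame with `session_id`,
#'   `theta_coherence`, `outcome`, `delay_category` (pooled over
#'   sessions).
#' @param split_by_delay compute per delay category with the
#'   >= `min_trials`-per-cell filter.
#' @param min_trials per-cell minimum for the split variant.
#' @return list with `scores` (data.frame: session_id, [delay_category,]
#'   score) and `excluded` (session ids).
#' @export
difference_scores <- function(trial_coherence, split_by_delay = FALSE,
                              min_trials = 3) {
  tc <- trial_coherence
  sessions <- unique(tc$session_id)
  scores <- list(); excluded <- character()
  for (sid in sessions) {
    s <- tc[tc$session_id == sid, ]
    if (!split_by_delay) {
      ne <- sum(s$outcome == "error"); nc <- sum(s$outcome == "correct")
      if (ne < 1 || nc < 1) { excluded <- c(excluded, sid); next }
      mc <- mean(s$theta_coherence[s$outcome == "correct"])
      if (mc <= 0) stop("undefined-score error: zero correct-trial mean in ", sid, call. = FALSE)
      scores[[sid]] <- data.frame(
        session_id = sid,
        score = mean(s$theta_coherence[s$outcome == "error"]) / mc,
        stringsAsFactors = FALSE)
    } else {
      cells <- table(factor(s$outcome, OUTCOMES),
                     factor(s$delay_category, c("short", "long")))
      if (any(cells < min_trials)) { excluded <- c(excluded, sid); next }
      rows <- lapply(c("short", "long"), function(d) {
        sd_ <- s[s$delay_category == d, ]
        data.frame(session_id = sid, delay_category = d,
                   score = mean(sd_$theta_coherence[sd_$outcome == "error"]) /
                           mean(sd_$theta_coherence[sd_$outcome == "correct"]),
                   stringsAsFactors = FALSE)
      })
      scores[[sid]] <- do.call(rbind, rows)
    }
  }
  list(scores = if (length(scores)) do.call(rbind, c(scores, list(make.row.names = FALSE)))
                else data.frame(session_id = character(), score = numeric()),
       excluded = excluded)
}

#' Peri-event cohereogram for one lead pair
#'
#' Sliding-window magnitude-squared coherence around each trial start,
#' averaged over trials within each outcome class.
#'
#' @param session a `session_recording`.
#' @param acc_lead,hpc_lead row indices (or lead_ids) of the pair.
#' @param window c(before, after) in s around trial start.
#' @param step_s step between window centers (default 0.5 s).
#' @param win_s width of each coherence window (default 2 s, i.e. 3
#'   segments of 1000 ms at 50% overlap).
#' @param max_freq truncate frequencies (Hz).
#' @param notch apply the 60 Hz notch first.
#' @return list with `t` (s rel. trial start), `freqs`, and `c`, a named
#'   list per outcome class of [n_freqs x n_steps] mean coherence (NULL
#'   for a class with no complete windows, with a warning).
#' @export
peri_event_cohereogram <- function(session, acc_lead, hpc_lead,
                                   window = c(-10, 4), step_s = 0.5,
                                   win_s = 2, max_freq = 100, notch = TRUE) {
  fs <- session$sample_rate
  idx <- function(l) if (is.character(l)) match(l, session$leads$lead_id) else l
  xa <- session$signals[idx(acc_lead), ]
  xh <- session$signals[idx(hpc_lead), ]
  if (notch) { xa <- notch_60hz(xa, fs); xh <- notch_60hz(xh, fs) }
  n <- length(xa)
  centers <- seq(window[1], window[2], by = step_s)
  tt <- build_trial_table(session$events)
  acc_c <- list(correct = NULL, error = NULL)
  counts <- c(correct = 0, error = 0)
  freqs <- NULL
  for (r in seq_len(nrow(tt))) {
    t0 <- tt$trial_start_s[r]
    lo <- (t0 + window[1] - win_s / 2) * fs
    hi <- (t0 + window[2] + win_s / 2) * fs
    if (lo < 0 || hi > n) next  # window not fully inside the session
    mats <- NULL
    for (k in seq_along(centers)) {
      i0 <- round((t0 + centers[k] - win_s / 2) * fs) + 1L
      i1 <- i0 + round(win_s * fs) - 1L
      cs <- msc(xa[i0:i1], xh[i0:i1], fs, max_freq = max_freq)
      if (is.null(mats)) {
        freqs <- cs$freqs
        mats <- matrix(0, length(freqs), length(centers))
      }
      mats[, k] <- cs$c
    }
    oc <- tt$outcome[r]
    acc_c[[oc]] <- if (is.null(acc_c[[oc]])) mats else acc_c[[oc]] + mats
    counts[oc] <- counts[oc] + 1
  }
  if (sum(counts) == 0) warning("no trials with complete peri-event windows")
  for (oc in names(acc_c)) {
    if (counts[oc] > 0) acc_c[[oc]] <- acc_c[[oc]] / counts[oc]
  }
  list(t = centers, freqs = freqs, c = acc_c, n_trials = counts)
}
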