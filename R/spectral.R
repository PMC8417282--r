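# Spectral decomposition: notch filtering, short-time PSD frames,
# normalized session spectra, band power and theta/delta ratios.

#' Default frequency bands (Hz)
#'
#' Delta and theta follow the rodent conventions this pipeline assumes
#' (1-4 and 6-13 Hz). The slow/fast gamma edges are the conventional CA1
#' bands, chosen to exclude 60 Hz line noise; both are configurable
#' wherever a band is accepted.
#'
#' @param name one of "delta", "theta", "slow_gamma", "fast_gamma".
#' @return list with `name`, `lo`, `hi`.
#' @export
band_def <- function(name = c("delta", "theta", "slow_gamma", "fast_gamma")) {
  name <- match.arg(name)
  edges <- list(delta = c(1, 4), theta = c(6, 13),
                slow_gamma = c(25, 55), fast_gamma = c(65, 100))[[name]]
  list(name = name, lo = edges[1], hi = edges[2])
}

#' Custom frequency band
#' @param name label.
#' @param lo,hi band edges in Hz, 0 < lo < hi.
#' @export
band <- function(name, lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("band requires 0 < lo < hi", call. = FALSE)
  list(name = name, lo = lo, hi = hi)
}

#' Notch-filter 60 Hz line noise
#'
#' Zero-phase (forward-backward) second-order Butterworth band-stop at
#' 58-62 Hz. Attenuation at 60 +/- 0.5 Hz exceeds 20 dB while the 1-50 Hz
#' passband is preserved within a fraction of a dB.
#'
#' @param x numeric signal vector.
#' @param sample_rate Hz, must exceed 120.
#' @return filtered signal, same length.
#' @export
notch_60hz <- function(x, sample_rate) {
  if (sample_rate <= 120) stop("parameter error: sample_rate must exceed 120 Hz", call. = FALSE)
  bt <- signal::butter(2, c(58, 62) / (sample_rate / 2), type = "stop")
  as.numeric(signal::filtfilt(bt, x))
}

#' Short-time power spectral density frames
#'
#' Hamming-tapered, mean-detrended windows of `window_ms` with
#' `overlap_ms` of overlap (hop = window - overlap), one-sided PSD per
#' frame. At the default 1000 ms window and 1 kHz sampling, the frequency
#' grid has 1 Hz resolution and the hop is 800 ms.
#'
#' @param x numeric signal.
#' @param sample_rate Hz.
#' @param window_ms window length, ms.
#' @param overlap_ms overlap between consecutive windows, ms.
#' @return `spectrogram_frames`: list with `power` [n_freqs x n_frames],
#'   `freqs` (Hz), `frame_times` (s, window centers), `window_ms`,
#'   `overlap_ms`, `sample_rate`.
#' @export
compute_spectrogram <- function(x, sample_rate, window_ms = 1000, overlap_ms = 200) {
  nwin <- round(window_ms * sample_rate / 1000)
  hop <- round((window_ms - overlap_ms) * sample_rate / 1000)
  if (hop < 1) stop("parameter error: overlap must be smaller than the window", call. = FALSE)
  n <- length(x)
  if (n < nwin) stop("length error: signal shorter than one window", call. = FALSE)
  n_frames <- floor((n - nwin) / hop) + 1L
  w <- signal::hamming(nwin)
  scale <- 2 / (sample_rate * sum(w^2))  # one-sided PSD density scaling
  n_freq <- nwin %/% 2 + 1L
  pw <- matrix(0, n_freq, n_frames)
  starts <- (seq_len(n_frames) - 1L) * hop
  for (k in seq_len(n_frames)) {
    seg <- x[(starts[k] + 1L):(starts[k] + nwin)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(n_freq)])^2 * scale
    sp[1] <- sp[1] / 2
    if (nwin %% 2 == 0) sp[n_freq] <- sp[n_freq] / 2
    pw[, k] <- sp
  }
  structure(
    list(power = pw,
         freqs = (seq_len(n_freq) - 1L) * sample_rate / nwin,
         frame_times = (starts + nwin / 2) / sample_rate,
         window_ms = window_ms, overlap_ms = overlap_ms,
         sample_rate = sample_rate),
    class = "spectrogram_frames"
  )
}

#' Session-averaged normalized power spectrum of one lead
#'
#' Frame powers are averaged over the session and expressed as a
#' proportion of total power over `norm_range` (the summary convention of
#' this pipeline: 1-100 Hz for spectral summaries, 1-50 Hz for decoding
#' features).
#'
#' @param frames a `spectrogram_frames`.
#' @param norm_range length-2 Hz interval over which the spectrum is kept
#'   and normalized to sum to one.
#' @param lead_id optional label carried through to decoding.
#' @return `lead_spectrum`: list with `freqs`, `norm_power` (sums to 1
#'   over `norm_range`), `norm_range`, `lead_id`.
#' @export
session_psd <- function(frames, norm_range = c(1, 100), lead_id = NA_character_) {
  mp <- rowMeans(frames$power)
  keep <- frames$freqs >= norm_range[1] & frames$freqs <= norm_range[2]
  if (!any(keep)) stop("parameter error: norm_range outside frequency grid", call. = FALSE)
  tot <- sum(mp[keep])
  if (tot <= 0) stop("normalization error: zero total power in range", call. = FALSE)
  structure(
    list(freqs = frames$freqs[keep], norm_power = mp[keep] / tot,
         norm_range = norm_range, lead_id = lead_id),
    class = "lead_spectrum"
  )
}

#' Mean power in a frequency band
#'
#' Mean of the PSD over the band's inclusive frequency bins: per frame
#' for `spectrogram_frames` (a series), a scalar for a `lead_spectrum`.
#'
#' @param x `spectrogram_frames` or `lead_spectrum`.
#' @param band a band as from [band_def()] or [band()].
#' @return numeric series (one value per frame) or scalar.
#' @export
band_power <- function(x, band) UseMethod("band_power")

#' @export
band_power.spectrogram_frames <- function(x, band) {
  keep <- x$freqs >= band$lo & x$freqs <= band$hi
  if (!any(keep)) stop("parameter error: band outside frequency grid", call. = FALSE)
  colMeans(x$power[keep, , drop = FALSE])
}

#' @export
band_power.lead_spectrum <- function(x, band) {
  keep <- x$freqs >= band$lo & x$freqs <= band$hi
  if (!any(keep)) stop("parameter error: band outside frequency grid", call. = FALSE)
  mean(x$norm_power[keep])
}

#' Theta/delta ratio
#'
#' Elementwise ratio of theta to delta band power; series in, series out.
#'
#' @param theta_power,delta_power numeric, equal length, delta > 0.
#' @return theta_power / delta_power.
#' @export
td_ratio <- function(theta_power, delta_power) {
  if (any(delta_power <= 0)) stop("undefined-ratio error: delta power must be positive", call. = FALSE)
  theta_power / delta_power
}

#' Session theta/delta ratio of one lead
#'
#' The session scalar is the ratio of session-mean band powers (mean
#' theta power divided by mean delta power), not the mean of per-frame
#' ratios.
#'
#' @param frames a `spectrogram_frames`.
#' @param theta,delta band definitions.
#' @return scalar ratio.
#' @export
session_td_ratio <- function(frames, theta = band_def("theta"), delta = band_def("delta")) {
  td_ratio(mean(band_power(frames, theta)), mean(band_power(frames, delta)))
}

#' Per-lead session spectra and TD ratios for a whole session
#'
#' Applies the notch filter, the short-time decomposition and the session
#' summaries to every lead of a session.
#'
#' @param session a `session_recording`.
#' @param norm_range normalization interval for [session_psd()].
#' @param window_ms,overlap_ms framing parameters.
#' @param notch apply [notch_60hz()] first (default TRUE).
#' @return list with `spectra` (list of `lead_spectrum` keyed by lead_id)
#'   and `summary` (data.frame: lead metadata + delta/theta power of the
#'   normalized spectrum and the session TD ratio).
#' @export
session_spectral_profile <- function(session, norm_range = c(1, 100),
                                     window_ms = 1000, overlap_ms = 200,
                                     notch = TRUE) {
  fs <- session$sample_rate
  spectra <- vector("list", nrow(session$leads))
  names(spectra) <- session$leads$lead_id
  summ <- session$leads
  summ$delta_power <- summ$theta_power <- summ$td_ratio <- NA_real_
  for (i in seq_len(nrow(session$leads))) {
    x <- session$signals[i, ]
    if (notch) x <- notch_60hz(x, fs)
    fr <- compute_spectrogram(x, fs, window_ms, overlap_ms)
    spectra[[i]] <- session_psd(fr, norm_range, lead_id = session$leads$lead_id[i])
    summ$delta_power[i] <- band_power(spectra[[i]], band_def("delta"))
    summ$theta_power[i] <- band_power(spectra[[i]], band_def("theta"))
    summ$td_ratio[i] <- session_td_ratio(fr)
  }
  list(spectra = spectra, summary = summ)
}
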