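# Cross-frequency phase-amplitude coupling: band-limited phase and
# amplitude extraction, the entropy-based modulation index, and
# comodulograms.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Doubles positive frequencies and zeroes negative ones, so the result's
#' modulus is the instantaneous amplitude and its argument the
#' instantaneous phase.
#'
#' @param x real signal.
#' @return complex analytic signal, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase FIR (Hamming-windowed) applied with zero net phase by
#' multiplying the spectrum with the squared filter magnitude — the
#' frequency-domain equivalent of forward-backward filtering, chosen for
#' speed on session-length signals. The order is `cycles` cycles of the
#' band's low edge, lengthened when needed so the transition width stays
#' below half the bandwidth (narrow gamma bands would otherwise smear
#' into their neighbours).
#'
#' @param x signal.
#' @param sample_rate Hz.
#' @param lo,hi band edges (Hz), inside (0, Nyquist).
#' @param cycles filter length in cycles of `lo`.
#' @return filtered signal, same length, zero phase shift.
#' @export
bandpass_filter <- function(x, sample_rate, lo, hi, cycles = 3) {
  if (!(lo > 0 && hi > lo && hi < sample_rate / 2)) {
    stop("parameter error: band must satisfy 0 < lo < hi < Nyquist", call. = FALSE)
  }
  ntaps <- fir_taps(sample_rate, lo, hi, cycles, length(x))
  b <- signal::fir1(ntaps, c(lo, hi) / (sample_rate / 2), type = "pass")
  nfft <- stats::nextn(length(x) + 2 * ntaps, c(2, 3, 5))
  H <- Mod(fft(c(b, rep(0, nfft - length(b)))))^2
  y <- Re(fft(fft(c(x, rep(0, nfft - length(x)))) * H, inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# FIR order: `cycles` cycles of the low edge, or enough taps to keep the
# Hamming transition width (~3.3 fs / N) under half the bandwidth.
fir_taps <- function(sample_rate, lo, hi, cycles, n) {
  ntaps <- ceiling(max(cycles * sample_rate / lo,
                       6.6 * sample_rate / (hi - lo)))
  ntaps <- ntaps + ntaps %% 2  # even order -> odd-length symmetric kernel
  if (ntaps + 1 >= n) {
    stop("parameter error: band too narrow for filter order at this signal length",
         call. = FALSE)
  }
  ntaps
}

# Band-pass + analytic signal in a single padded FFT pair: the squared
# FIR magnitude response times the Hilbert step mask. Equivalent to
# bandpass_filter() followed by analytic_signal() up to edge effects of
# the zero padding, at half the cost on session-length signals.
bandpass_analytic <- function(x, sample_rate, lo, hi, cycles = 3) {
  if (!(lo > 0 && hi > lo && hi < sample_rate / 2)) {
    stop("parameter error: band must satisfy 0 < lo < hi < Nyquist", call. = FALSE)
  }
  ntaps <- fir_taps(sample_rate, lo, hi, cycles, length(x))
  b <- signal::fir1(ntaps, c(lo, hi) / (sample_rate / 2), type = "pass")
  nfft <- stats::nextn(length(x) + 2 * ntaps, c(2, 3, 5))
  H <- Mod(fft(c(b, rep(0, nfft - length(b)))))^2
  h <- numeric(nfft)
  h[c(1, nfft / 2 + 1)] <- 1
  h[2:(nfft / 2)] <- 2
  y <- fft(fft(c(x, rep(0, nfft - length(x)))) * H * h, inverse = TRUE) / nfft
  y[seq_along(x)]
}

#' Band-limited phase and amplitude of a signal
#'
#' Band-passes the two bands with [bandpass_filter()] and takes the
#' analytic-signal angle (phase band) and magnitude (amplitude band).
#'
#' @param x signal.
#' @param sample_rate Hz.
#' @param phase_band,amp_band bands as from [band_def()] or [band()].
#' @return list with `phase` (radians in (-pi, pi]), `amplitude` (>= 0),
#'   and the two bands.
#' @export
extract_phase_amplitude <- function(x, sample_rate, phase_band, amp_band) {
  list(phase = Arg(bandpass_analytic(x, sample_rate, phase_band$lo, phase_band$hi)),
       amplitude = Mod(bandpass_analytic(x, sample_rate, amp_band$lo, amp_band$hi)),
       bands = list(phase = phase_band, amp = amp_band))
}

#' Entropy-based modulation index
#'
#' Phases are binned into `n_bins` equal bins over (-pi, pi]; the mean
#' amplitude per bin is normalized to a distribution P and
#' MI = (log N - H(P)) / log N with H the Shannon entropy (natural log,
#' 0 log 0 = 0). MI = 0 for phase-independent amplitude, 1 when all
#' amplitude mass falls in a single bin.
#'
#' @param phase radians.
#' @param amplitude non-negative, same length (>= 10 * n_bins samples).
#' @param n_bins number of phase bins (default 18).
#' @return scalar in [0, 1].
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) {
    stop("parameter error: phase and amplitude lengths differ", call. = FALSE)
  }
  if (length(phase) < 10 * n_bins) {
    stop("parameter error: series too short for ", n_bins, " phase bins", call. = FALSE)
  }
  if (all(amplitude == 0)) stop("undefined-MI error: all-zero amplitude", call. = FALSE)
  bin <- pmin(n_bins, pmax(1L, ceiling((phase + pi) / (2 * pi) * n_bins)))
  cnt <- tabulate(bin, n_bins)
  tot <- numeric(n_bins)
  sums <- rowsum(amplitude, bin)
  tot[as.integer(rownames(sums))] <- sums
  pj <- ifelse(cnt > 0, tot / pmax(1L, cnt), 0)  # mean amplitude per phase bin
  pj <- pj / sum(pj)
  h <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Modulation index of one band pair of a signal
#'
#' @inheritParams extract_phase_amplitude
#' @param n_bins phase bins for [modulation_index()].
#' @return scalar MI.
#' @export
pac_mi <- function(x, sample_rate, phase_band, amp_band, n_bins = 18) {
  pa <- extract_phase_amplitude(x, sample_rate, phase_band, amp_band)
  modulation_index(pa$phase, pa$amplitude, n_bins)
}

#' Comodulogram over a (phase frequency x amplitude frequency) grid
#'
#' MI for every grid pair; each center frequency is band-passed with the
#' given bandwidth around it.
#'
#' @param x signal.
#' @param sample_rate Hz.
#' @param phase_freqs,amp_freqs center-frequency grids (Hz).
#' @param phase_bw,amp_bw full bandwidths (Hz) of the phase and
#'   amplitude bands.
#' @param n_bins phase bins.
#' @return `mi_grid`: list with `phase_freqs`, `amp_freqs`, and `mi`
#'   [n_amp x n_phase], amplitude frequency in rows.
#' @export
comodulogram <- function(x, sample_rate, phase_freqs = seq(2, 12, 2),
                         amp_freqs = seq(20, 100, 10),
                         phase_bw = 4, amp_bw = 20, n_bins = 18) {
  phases <- lapply(phase_freqs, function(f) {
    Arg(bandpass_analytic(x, sample_rate, max(0.5, f - phase_bw / 2),
                          f + phase_bw / 2))
  })
  amps <- lapply(amp_freqs, function(f) {
    Mod(bandpass_analytic(x, sample_rate, max(0.5, f - amp_bw / 2),
                          min(sample_rate / 2 - 1, f + amp_bw / 2)))
  })
  mi <- matrix(NA_real_, length(amp_freqs), length(phase_freqs),
               dimnames = list(amp_freqs, phase_freqs))
  for (i in seq_along(amp_freqs)) {
    for (j in seq_along(phase_freqs)) {
      mi[i, j] <- modulation_index(phases[[j]], amps[[i]], n_bins)
    }
  }
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, mi = mi),
            class = "mi_grid")
}

#' Session-level modulation index per area and band pair
#'
#' MI is computed over the entire session for each lead and averaged
#' over an area's leads, one value per (session, area, pair). Default
#' pairs: delta->theta, theta->slow gamma, theta->fast gamma.
#'
#' @param session a `session_recording`.
#' @param pairs list of `list(phase = band, amp = band)`.
#' @param notch apply the 60 Hz notch first.
#' @return data.frame: area, pair, mi (area mean), n_leads.
#' @export
session_pac_summary <- function(session,
                                pairs = list(
                                  delta_theta = list(phase = band_def("delta"),
                                                     amp = band_def("theta")),
                                  theta_slow_gamma = list(phase = band_def("theta"),
                                                          amp = band_def("slow_gamma")),
                                  theta_fast_gamma = list(phase = band_def("theta"),
                                                          amp = band_def("fast_gamma"))),
                                notch = TRUE) {
  fs <- session$sample_rate
  res <- list()
  for (a in unique(session$leads$area)) {
    idx <- which(session$leads$area == a)
    mi_lead <- matrix(NA_real_, length(idx), length(pairs))
    for (k in seq_along(idx)) {
      x <- session$signals[idx[k], ]
      if (notch) x <- notch_60hz(x, fs)
      for (p in seq_along(pairs)) {
        mi_lead[k, p] <- pac_mi(x, fs, pairs[[p]]$phase, pairs[[p]]$amp)
      }
    }
    res[[a]] <- data.frame(area = a, pair = names(pairs),
                           mi = colMeans(mi_lead), n_leads = length(idx),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, res)
}
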