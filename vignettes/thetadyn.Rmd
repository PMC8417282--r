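---
title: "thetadyn: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thetadyn: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetadyn)
```

This vignette is the package's account of its science: the data model,
the estimators and their numerical choices, the generative model behind
the synthetic cohorts, and what the validation on synthetic data does
and does not establish.

## The analysis problem

Rodents performing a delayed-alternation T-maze task are sequestered in
a delay box for a random interval (uniform on 5–45 s here), then run a
circuit to the alternating reward arm. During the task, local field
potentials are recorded from hippocampal CA1 and the anterior cingulate
cortex — 16 leads per session, 4 per area per hemisphere, at 1 kHz —
along with the animal's position. The scientific questions this
pipeline serves are about oscillatory state and inter-area
communication: how the delta (1–4 Hz) / theta (6–13 Hz) balance differs
between a control and a treatment group (here labelled "STZ" after the
hyperglycemia model), how strongly slow-oscillation phase modulates
gamma amplitude, whether ACC–hippocampal theta coherence during the
delay predicts trial outcome, and whether the per-lead spectral pattern
is consistent enough to identify a lead's area and group — a "spectral
phenotype".

## Data model

A session (`session_recording`) bundles the signal matrix, lead
metadata, position samples and the trial event log, with invariants
enforced at construction: a shared time base, strictly increasing
position timestamps inside the recording, ordered non-overlapping
trials with `delay_start < trial_start < choice_time < return_time`,
and unique lead ids. Times are seconds from session start; sample
index = round(t × rate); intervals are half-open `[start, end)`.

The on-disk format is deliberately plain: `signals.f32` (raw
little-endian float32, lead-major) with a JSON sidecar, and CSV tables
for leads, positions and events. Signals are quantized to float32 at
construction and numeric CSV columns are written as `%.17g`, so a
session round-trips bit-exactly (`read(write(s))` is `identical` to
`s`, and rewriting produces byte-identical directories).

Delays shorter than 20 s are "short", otherwise "long". The boundary
value 20 s is assigned to "long" so the two categories partition all
trials; the conventional definition leaves the boundary point
unspecified, and a deterministic total rule matters more than which
side it lands on.

## Spectral estimation

Each lead is notch-filtered (zero-phase order-2 Butterworth band-stop,
58–62 Hz) and decomposed with Hamming-tapered, mean-detrended 1000 ms
windows with 200 ms overlap (800 ms hop). At 1 kHz this gives 1 Hz
resolution, the natural grid for the 1–100 Hz summaries. The session
spectrum of a lead is the frame-mean PSD normalized to unit mass over a
stated range: 1–100 Hz for spectral summaries, 1–50 Hz for decoding
features (the 50 Hz cap keeps residual line noise out of the feature
space). Band power is the mean PSD over a band's inclusive 1 Hz bins.

The session TD ratio is the ratio of session-mean band powers, not the
mean of per-frame ratios: the per-frame ratio is noisy and heavy-tailed
when delta power is momentarily small, while the ratio of means is
stable and scale-invariant. Per-frame TD series are still available for
peri-event analyses.

Peri-event analyses (TD ratios around trial start, window −10 s to
+4 s) use a dedicated 1000 ms / 500 ms-hop spectrogram so that group
comparisons run at 500 ms steps; the 800 ms session hop and the 500 ms
peri-event step are both honored, each in its own context.

## Phase–amplitude coupling

The modulation index of a (phase band, amplitude band) pair is
Tort-style: band-limit both, take the analytic signal's angle and
modulus, bin phases into N = 18 equal bins, normalize the mean
amplitude per bin to a distribution P, and report
MI = (ln N − H(P)) / ln N, which is 0 for phase-independent amplitude
and 1 when all amplitude mass falls in one bin. MI is computed over the
entire session per lead and averaged over an area's leads, one value
per (session, area, pair); default pairs are delta→theta,
theta→slow-gamma and theta→fast-gamma. Gamma edges (25–55 and
65–100 Hz) are the conventional rodent CA1 bands, chosen to exclude
60 Hz; both are configurable.

Filtering is linear-phase FIR (Hamming-windowed `fir1`) applied with
zero net phase by multiplying the signal spectrum with the squared
filter magnitude — the frequency-domain equivalent of forward-backward
filtering, chosen because session-length signals make time-domain
convolution with thousands of taps the bottleneck. The band-pass and
Hilbert steps are fused into one padded FFT pair. The filter order is
3 cycles of the band's low edge, lengthened when necessary so the
Hamming transition width (≈ 3.3·fs/N) stays below half the bandwidth:
with the low-edge rule alone, a 1 kHz gamma band gets ~100 taps and a
~33 Hz transition band, which smears comodulogram columns enough to
displace a planted (8 Hz, 40 Hz) coupling peak into the neighbouring
amplitude bin. An amplitude band must also be wider than twice the
modulating frequency (sidebands at f_c ± f_m must pass), hence the
20 Hz default comodulogram amplitude bandwidth.

## Coherence

Magnitude-squared coherence is Welch-based:
C_xy(f) = |P_xy(f)|² / (P_xx(f) P_yy(f)) with Hamming segments; it
requires at least two segments (one segment gives the degenerate
estimate C ≡ 1, reported as an error). Per-trial theta coherence uses
the last 10 s of the delay plus the first 2 s of the run — one
concatenated window, 1000 ms segments at 50% overlap (~23 segments),
averaged over 6–13 Hz and then over all ipsilateral ACC×HPC lead pairs.
Trials with delays under 10 s use the full available delay and are
flagged. The per-session difference score is mean error-trial coherence
divided by mean correct-trial coherence; the delay-split variant keeps
only sessions with at least 3 trials in each (outcome × delay) cell and
reports the exclusions. Note that the Welch estimator is positively
biased at small segment counts; difference scores are ratios of
identically-biased quantities, which is why they remain informative at
the 12 s window.

## Decoding protocol

Features are each lead's normalized 1–50 Hz spectrum (renormalized to
unit mass after restriction). The classifier is a linear-kernel SVM
(cost 1, one-vs-one multi-class as in the common ECOC implementations;
`e1071::svm` provides the fitted ensemble) with Platt-style
score-to-probability calibration fitted on the training set for the
posterior summaries. No hyperparameter search is done: the protocol's
point is the information content of the features, not classifier
tuning. Training sets draw a fixed number of leads per class uniformly
without replacement; all remaining leads are the test set (pooled, not
re-balanced); held-out/training disjointness is asserted on every
iteration. The shuffled null permutes labels before the split, which
with four balanced classes concentrates held-out accuracy at 25% and
makes the three misclassification types (wrong group, wrong area, both)
equally likely. Leave-one-subject-out and leave-one-session-out
variants train on a fixed number of leads per class drawn from all
other units; the iteration count defaults to 100 per unit (a
cost-driven choice; the protocol is also commonly run at 1000).

## Statistics

Kruskal–Wallis H is computed from the rank formula with the tie
correction and the χ² approximation on k − 1 degrees of freedom; it is
cross-checked in the tests against `stats::kruskal.test` and, at small
n, against an exact permutation oracle. Running group comparisons of
peri-event TD ratios use the classical equal-variance one-way F at each
500 ms step with a Bonferroni-corrected mask (α/n_steps); the F values
are cross-checked against `anova(lm(...))` at every step.

## The synthetic cohort generator

Each lead's signal is

    x(t) = noise_amp · pink(t)
         + a_δ(t) cos φ_δ(t)
         + a_θ(t) [ λ(t) cos φ_sh(t) + (1 − λ(t)) cos φ_θ(t) ]
         + Σ_g A_g [ 1 + κ_g cos φ_carrier(t) ] cos φ_g(t)

with a_δ(t) = delta_amp · max(0, 1 + β_δ v̂(t)),
a_θ(t) = theta_amp · (1 + β_θ v̂(t)) · (1 + κ_δθ cos φ_δ(t)), v̂ the
running speed normalized to [0, 1], and φ_carrier the phase of the
mixed theta component. The 1/f background is spectrally shaped white
noise (exponent 1 by default). Oscillator phases integrate an
instantaneous frequency carrying two perturbations: fast jitter
(SD 0.1 Hz, 10 Hz knots) that widens the spectral line, and a slow
drift (SD 0.3 Hz, 0.2 Hz knots). The slow drift is essential for the
coherence analyses: fast jitter alone integrates away, leaving two
nominally independent 8 Hz oscillators phase-locked over 12 s windows
and erasing the contrast between planted mixing weights; with the
drift, independent oscillators decohere within a few seconds while the
shared-source coherence survives (it cancels in the phase difference).

Within a hemisphere, all ACC and HPC leads mix one shared theta phase
φ_sh with weight λ (`coherence_mix`), planting inter-area coherence.
During each error trial's delay window (delay period plus the first
2 s of the run) λ is shifted by `coherence_outcome_shift`, multiplied
by `coherence_long_multiplier` on long-delay trials, and clipped to
[0, 1]. The control preset shifts λ down on errors (difference scores
< 1); the STZ-like preset shifts it up, more on long delays
(difference scores > 1) — mirroring the direction, not the magnitude,
of the effect the pipeline is designed to detect.

Behavior: delays i.i.d. uniform on [5, 45] s; outcomes Bernoulli with
P(correct | group, delay category); positions trace the T-maze circuit
(74 cm stem, 63.5 cm arms) with stationary delay epochs and smooth
run/return epochs whose speed profile is group-independent by
construction, so any group difference a speed-coupled measure shows is
attributable to the planted signal parameters, not behavior.

Preset effect sizes (`default_phenotypes()`) are package defaults
chosen once to make every planted direction comfortably detectable at
cohort scale — e.g. control HPC theta_amp 6 / delta_amp 2 against
STZ-like 3.5 / 4.5, κ_θ→slowγ 0.20 vs 0.50, λ 0.6 vs 0.75 with shifts
−0.25 vs +0.15×1.5 — and are not estimates of any measured quantity.
The `separable_phenotypes()` preset gives the four classes distinct
spectral peaks over a weak background and exists purely as a decoding
oracle.

Determinism: every (session, hemisphere, lead, purpose) tuple draws
from its own stream, seeded by a fixed multiply-accumulate hash of the
master seed modulo 2³¹ − 1, so identical seeds give byte-identical
cohorts and enlarging a cohort never perturbs existing sessions. R's
Mersenne–Twister makes this platform-stable.

## Problem sizes

The shipped analyses and tests run at deliberately scaled-down study
conditions, chosen once: 3 subjects × 2 sessions per group and 14
trials per session for the effect-recovery cohort; 12 two-trial
sessions for the decoding cohort (PSD features need signal length, not
trials); 200–250 iterations for null distributions; 100 iterations for
sweeps; 220 s of signal for single-lead coupling checks. The package
defaults (`cohort_config()`) describe a full-scale cohort — 3 control
and 5 treated subjects, ~35 sessions of 30 trials — matching the design
this pipeline targets. One visible scale effect: with 14 trials per
session the ≥ 3-trials-per-cell filter of the delay-split difference
scores excludes most sessions (at ~35 trials per session it retains
most), so the split variant is exercised in unit tests with constructed
tables rather than on the small cohort.

## What the synthetic validation shows — and does not

Passing tests establish that each estimator recovers the sign and
ordering of effects planted in a generative model that matches the
analysis assumptions: sinusoidal narrow-band oscillators, amplitude
modulation as explicit multiplicative coupling, coherence as a shared
phase source, 1/f noise. Real LFPs violate all of these in degree —
asymmetric theta waveforms (which can masquerade as harmonically
structured PAC), nonstationary noise floors, volume conduction,
movement artifacts, electrode drift. The pipeline's robustness to those
is not established here, and the generator deliberately makes no
attempt to fit its parameters to any animal's data. Sharp-wave-ripple
detection and spike analyses are out of scope.

## Known limitations

- Welch coherence at ~23 overlapped segments has a noticeable positive
  bias; absolute per-trial coherence values should be compared only
  within matched window configurations.
- The frequency-domain zero-phase filter realizes the squared FIR
  magnitude exactly but treats the signal as zero-padded, so a few
  filter lengths at each session edge are attenuated; session-level
  summaries are insensitive to this, single-trial analyses at the very
  start or end of a recording are not.
- Posterior probabilities from Platt calibration are a convention, not
  calibrated class frequencies, especially for small training sets.
- `fir1` band edges are −6 dB points; nominal band edges are therefore
  soft by half the transition width.
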