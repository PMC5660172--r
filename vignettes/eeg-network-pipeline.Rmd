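---
title: "Network oscillations, connectivity and evoked potentials: methods"
author: "tauconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network oscillations, connectivity and evoked potentials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, the numerical choices behind them,
and what validation on simulated data does and does not establish.

## Scientific setting

The package analyses multichannel rodent EEG from a hippocampal-prefrontal
montage (bilateral prefrontal cortex, CA1 and CA3) in experiments that
compare a control ("buffer") group against a tau-seeded ("K18") group. The
physiological readouts are the ones known to degrade early under evolving
tau pathology: relative theta power, prefrontal-hippocampal theta
coherence, theta-gamma phase-amplitude coupling, the auditory
mismatch-negativity (MMN) component complex, and evoked gamma oscillations
in the passive oddball paradigm. An immunohistochemistry module quantifies
DAB-stained (e.g. phospho-tau or parvalbumin) area fractions from RGB
micrographs. Because no public recordings accompany this kind of study, a
first-class synthetic-data generator reproduces the essential statistical
structure of the recordings with known ground truth, and the whole pipeline
is validated against that ground truth.

## Preprocessing

Recordings are held as channels x samples matrices in microvolts
(`recording()`), read and written as EDF (16-bit, one-second records) or
delimited text. Standard preprocessing is a zero-phase FIR notch at 50 Hz
(4 Hz stop band) and a zero-phase FIR band-pass of 1-100 Hz, mirroring a
typical acquisition chain. Both filters are linear-phase kernels
(Hamming-windowed designs from `signal::fir1`) applied in two centred
passes, which is equivalent to forward-backward filtering: the phase
response is identically zero, so component latencies of evoked potentials
are untouched. Orders are chosen from the transition width (`3.3 * fs /
transition`), giving more than 40 dB of stop-band attenuation per
specification; the band-stop kernel is renormalized so its DC gain is
exactly 1. Epochs are cut on half-open 4 s boundaries; an epoch is rejected
when any sample exceeds an absolute threshold (default 1000 µV) or any
channel is flat (variance < 1e-3 µV²). The original study's artifact and
vigilance-scoring criteria are not published in detail; the threshold rule
is a deliberately simple, configurable stand-in, and vigilance states are
accepted as pre-computed labels, never inferred.

## Spectra

`power_spectrum()` is a Welch estimator: Hann-tapered FFTs of 4 s windows
with 50% overlap, averaged over windows and epochs. Native bins (0.25 Hz at
the default window) are aggregated onto a 1 Hz grid by summing bins whose
centres fall in `[f - 0.5, f + 0.5)`; absolute power is in µV² per 1 Hz
bin, and relative power divides by the total over the analysis range
(1-100 Hz by default; 1-50 Hz sleep-study spectra are obtained with
`fmax = 50`, in which case the relative normalization uses that range).
Band summaries use half-open intervals, delta 1-4, theta 4-12, gamma
25-100 Hz. `longitudinal_ratio()` divides each session's absolute power by
the first session's, bin by bin; zero reference bins yield `NA` rather than
infinities.

## Coherence

`msc_coherence()` computes `|S_AB|^2 / (S_AA S_BB)` with the auto- and
cross-spectra averaged over the same Hann windows *before* the quotient --
averaging after would give the trivial value 1. The quotient is evaluated
at native resolution and then averaged into 1 Hz bins; this order preserves
the textbook small-sample behaviour (unrelated signals average to ~1/M with
M windows), which the tests verify directly. No bias correction is applied;
the bias is documented and covered by tests instead. Group differences in
band-averaged coherence use the pooled-variance independent-samples t-test
with its confidence interval (`group_compare()`).

## Phase-amplitude coupling

For a phase frequency `f_L` and amplitude frequency `f_H`, the signal is
band-passed around each (zero-phase FIR), the analytic signal gives the
phase `phi_L(t)` and envelope `A_H(t)`, and the modulation index is
`MI = |mean(A_H(t) exp(i phi_L(t)))|`. For an envelope
`A0 (1 + kappa cos(phi))` over whole cycles, `MI = kappa A0 / 2` exactly --
the tests hold the implementation to this closed form within 1%.
Comodulograms cover 2-12 Hz in steps of 2 (phase) by 10-200 Hz in steps of
5 (amplitude), 234 cells. Phase bands are 2 Hz wide; amplitude bands are
`max(10, 2 * f_L_max)` = 24 Hz wide so that the modulation side-bands at
`f_H +/- f_L` are admitted, and their FIR transition width is a quarter of
the bandwidth so those side-bands pass at full gain. One filter length at
each end of every analytic series is excluded as edge region.

Significance uses 50 surrogates per cell, built by circularly time-shifting
the amplitude series against the phase series by random offsets of at least
1 s; this preserves both spectra while destroying their alignment. All
shifted correlations are obtained at once from one FFT-based circular
cross-correlation per cell. Two conditions must hold for a cell to be
significant at Bonferroni-corrected level `alpha / 234`:

1. the z-score `(MI - mean_surr) / sd_surr` exceeds the one-sided normal
   critical value, and
2. the Rayleigh-tail surrogate p-value clears the same level.

The second condition exists because the null MI is the modulus of a
complex-valued time average: asymptotically Rayleigh, not normal, so its
standardized upper tail is heavier than Gaussian and a z threshold alone
badly overstates significance (empirically, a family-wise false-positive
rate above 0.5 on white noise). The Rayleigh scale is estimated from the
surrogates (`sigma^2 = mean(s^2) / 2`) and the tail is compounded exactly
over the Gamma sampling noise of that estimate: with `m` surrogates,
`P(T > t) = (1 + t/m)^(-m)` for `T = MI^2 / (2 sigma^2)`. With this rule
the measured family-wise false-positive rate over hundreds of uncoupled
simulations is ~0.04, at the nominal level. Cells with zero surrogate
spread are reported undefined and never significant.

One structural limitation is worth knowing: when the phase signal is a
*deterministic* sinusoid, circular shifts only rotate the complex
correlation without changing its modulus, so surrogate spread collapses and
the test has essentially no power on such signals. Real (and simulated)
theta is a stochastic narrow-band process, for which the surrogates behave
normally; coupling recovery on clean deterministic test signals is instead
validated through the location of the comodulogram maximum.

## Oddball evoked potentials

Epochs span -50 to +450 ms around each stimulus; each epoch is corrected by
its own pre-stimulus baseline mean, then averaged per condition and, across
animals, into grand averages. Components are extracted per channel within
configurable windows -- defaults P1 [10, 30), N1 [30, 50), P2 [50, 100),
N2 [100, 200) ms; only the N1 window is anchored in published practice, the
others are conventional and configurable. Positive is upward; P components
are maxima, N components minima; a peak must be a strict local extremum
(monotone windows report "not found"), and ties resolve to the earlier
latency. The complex amplitudes are peak-to-peak: `N1-P1 = P1 - N1` and
`N1-P2 = P2 - N1`. Time-frequency maps use an analytic Morlet wavelet with
a fixed 6 cycles at every frequency, applied as a Gaussian mask in the
frequency domain; power is transform-then-average (total power), since
evoked and induced contributions are not separated -- a documented
simplification, switchable by averaging first if phase-locked-only power is
wanted. Evoked gamma is the mean power over 40-80 Hz in a post-stimulus
window.

## The synthetic-data generator

`simulate_recording()` builds each channel as: 1/f background (spectral
shaping of white noise, exponent 1, 50 µV RMS by default), band-limited
oscillators (Gaussian spectral masks; default one theta oscillator at 8 Hz,
2 Hz bandwidth, 10 µV RMS per channel), weighted shared sources (default
one theta-band source, 20 µV RMS, weight 1 into every channel -- giving
pairwise theta coherence of roughly 0.5), and, on the CA1 channels, a
70 Hz carrier whose envelope is `A0 (1 + kappa cos(phi_L))` with
`kappa = 0.8` and `A0 = 10` µV. The coupling phase is taken from the
channel's composite theta component (own oscillator plus shared-source
contributions in the f_L band), so the measured phase and the generated
envelope refer to the same oscillation. PAC carriers are deterministic
sinusoids so the closed-form MI is available; oscillators are stochastic.
The study's scales are not published; the microvolt defaults above are
declared conventions chosen to be plausible for epidural/depth rodent EEG.

Oddball sessions place `round(n_standard / (1 - p_deviant))` tones 4 s
apart (240 standards, 20% deviants by default), deviants seeded-randomly
with no two consecutive. Each stimulus adds a condition-specific ERP
template (Gaussian components; defaults P1 +30 µV at 20 ms, N1 -55 (deviant
-75) at 40 ms, P2 +35 at 80 ms, N2 -15 at 150 ms) plus a Gaussian-windowed
60 Hz burst around 100 ms (10 µV standard, 15 µV deviant). Template
amplitudes are in the tens of microvolts so that a single animal's 240-trial
average recovers them against the 50 µV background, consistent with
reported component-complex differences of order 10-30 µV. Because the ISI
is exactly 4 s, stimulus-locked averaging coherently samples background
components at multiples of 0.25 Hz; recovery is therefore assessed after
the standard 1-100 Hz acquisition band-pass, applied to recording and
template alike.

Group studies derive one seed per animal from a master seed (all
reproducible), and apply a multiplicative K18 effect profile: theta
oscillator RMS x0.7, shared-source weight x0.7 (so theta power and
coherence fall by the square, ~0.49), kappa x0.5, ERP template x0.7, evoked
gamma x0.7. `simulate_dab_image()` constructs micrographs in which exactly
`round(p * N_roi)` ROI pixels satisfy `(R - G)/B >= 0.5` with margin on
both sides of the threshold, so the recovered fraction is exact even after
8-bit quantization.

What passing on these simulations shows -- and does not. The generator
reproduces 1/f spectra, narrow-band rhythms, linear mixing, sinusoidal
envelope coupling and template-plus-noise evoked responses. It does not
model nonstationary vigilance dynamics, movement or electrode artifacts
beyond amplitude outliers, non-sinusoidal theta waveform asymmetry (a known
source of spurious PAC), volume-conduction phase structure, or biological
variance between animals beyond seed-to-seed realization noise. Passing
tests therefore establish correctness of the estimators under the stated
models, not robustness to every pathology of real recordings.

## Numerical and design choices

* Frequency intervals are half-open `[lo, hi)` everywhere; 1 Hz bins are
  labelled by integer centres.
* The coherence quotient is formed at native bins from window-averaged
  spectra, then averaged to 1 Hz -- this preserves the 1/M null level that
  the aggregate-first order would halve.
* Filters: odd-symmetric edge padding; kernel lengths capped by the signal
  length; two passes square the stop-band attenuation.
* Surrogate shifts are drawn without replacement when the lag pool allows;
  the observed MI is the lag-0 entry of the same correlation sequence.
* Circular FFT lengths are trimmed to the largest 5-smooth integer within
  the valid segment to keep R's mixed-radix FFT fast.
* Degenerate inputs fail loudly and early: empty ROIs, zero usable epochs,
  bands beyond Nyquist, fewer than two coherence windows, fewer than five
  slow-phase cycles.
* `B = 0` pixels in the DAB rule are defined non-positive and reported as a
  separate count.

## Problem sizes used in validation

The test-suite and acceptance computations run at desk scale, chosen as the
smallest sizes at which the stated tolerances are statistically meaningful:
500 Hz or 1 kHz sampling for coupling analyses (2 kHz for ERP timing
tests), 24-60 s segments for comodulograms, 60 s null runs for
false-positive calibration (100 runs), 200 Welch segments for the coherence
closed form, 240 trials for ERP averaging, cohorts of 9 vs 8 animals with
60-standard sessions for the end-to-end group contrast (10 replicate
studies), and 50 replicate zero-effect studies for t-test calibration.
The full-scale study settings (2 kHz, 3 h recordings, 45-minute PAC
segments, 240-standard sessions) are the package defaults.

## Known limitations

* Coherence and spectra assume a common sampling rate across channels and
  sessions.
* The surrogate test's power vanishes for strictly sinusoidal phase
  signals (see above); this is a property of circular-shift surrogates, not
  an implementation defect.
* Mixed-model group statistics with Hochberg/Dunnett adjustment, sleep
  staging, stain deconvolution and atlas registration are intentionally out
  of scope; only the independent-samples t comparison reported for
  coherence-type summaries is provided.
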