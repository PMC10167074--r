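---
title: "Stimulus-locked and cross-frequency analysis of neurophysiological recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-locked and cross-frequency analysis of neurophysiological recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropac)
```

# What the package computes

`neuropac` analyzes intracellular and extracellular electrophysiology
recordings along four axes:

* **time domain** — stimulus-locked trial segmentation, event-related
  potential (ERP) averaging, rectified-RMS z-score maps, and EPSP
  slope/latency measurement;
* **frequency domain** — Butterworth band filtering with a verifiable
  frequency response, analytic envelope and instantaneous phase, FFT
  magnitude spectra, Welch power spectral densities and (relative) band
  power;
* **time–frequency domain** — Morlet wavelet scalograms with trial
  averaging and display transforms;
* **cross-frequency coupling** — three phase–amplitude coupling (PAC)
  estimators (Kullback–Leibler modulation-index comodulograms, wavelet
  phase-binned power, and a cycle-detection variant for intermittent
  slow rhythms) plus two-channel phase coherence.

Everything operates on three S4 containers: a `Recording` (channels ×
samples with one sampling rate), a `ChannelSignal` (one trace), and a
`TrialSet` (trials × samples, time-locked to stimulus onsets with t = 0
at the stimulus). ABF1 and EDF files are read into `Recording` objects;
all analyses equally accept in-memory vectors via `channelSignal()`.

# The models and their assumptions

## Phase–amplitude coupling

The working model of PAC is that the phase $\phi_{f_p}(t)$ of a slow
("modulating") oscillation modulates the instantaneous amplitude
$A_{f_A}(t)$ of a faster ("modulated") oscillation, the classic
theta–gamma arrangement in hippocampus and cortex. All three indices
start from band-limited versions of the raw signal: the modulating band
is narrow (the phase of a broadband signal is not interpretable), the
modulated band broad enough to retain the side-bands $f_A \pm f_p$ that
carry the modulation.

Given the instantaneous phase and amplitude series:

* **KL modulation index** (`kl_mi`). Phases are binned into $N$ equal
  bins over $(-\pi, \pi]$ (default $N = 18$, i.e. 20°); the mean
  amplitude per bin, normalized to sum to one, forms a distribution
  $P$. The index is $(\log N - H(P)) / \log N$ with $H$ the Shannon
  entropy: 0 for a uniform profile, 1 when all amplitude concentrates
  in one bin.
* **Mean vector length** (`mvl`),
  $|\langle A e^{i\phi} \rangle| / \langle A \rangle$. The original
  amplitude-weighted resultant is scale-dependent; dividing by the mean
  amplitude makes it dimensionless so recordings of different gain are
  comparable.
* **Phase-locking value** (`plv`),
  $|\langle e^{i(\phi - \phi_A)} \rangle|$, where $\phi_A$ is the phase
  of the amplitude envelope itself band-filtered in the modulating
  band. PLV asks only whether the envelope fluctuates *in step* with
  the slow phase, not how deeply — it therefore saturates near 1 even
  at modest modulation depths and is best read as a detector, not a
  depth estimate.

The **comodulogram** evaluates one index over a grid of (phase
frequency × amplitude frequency) pairs. The modulating filter bandwidth
equals the grid step `pStep`; the modulated bandwidth is
`max(aStep, 2 * fp)` so both side-bands fit inside the passband.

One numerical choice matters more than any other here. Comodulogram
cells compete on the *relative* modulation of their envelopes, and a
relative measure is blind to overall attenuation. With gently sloped
IIR skirts, a cell whose passband catches the fast carrier only on its
skirt — attenuated toward side-band amplitude — produces an envelope
whose *relative* modulation is larger than in the correctly centered
cell, and the comodulogram peak drifts several grid steps off the true
amplitude frequency. The comodulogram therefore extracts its bands with
a zero-phase frequency-domain filter: unit gain in the passband,
raised-cosine roll-off over one `pStep`, zero beyond. The user-facing
filter module (below) keeps the classical Butterworth; the two serve
different purposes.

## Wavelet phase-binned power and the cycle method

`pacWaveletPhasePower()` replaces the Hilbert envelope of the modulated
band with Morlet wavelet power averaged across the band — the natural
choice when the modulated activity is broadband. `pacCycleBased()`
additionally restricts estimation to individual *cycles* of the
modulating rhythm: the band-filtered slow trace is segmented at its
troughs, and a trough-to-trough window is accepted only if

* its duration lies within 25% of the band's period range
  $[1/f_{high}, 1/f_{low}]$, and
* the rhythm is really there: the mean analytic envelope inside the
  window reaches at least a fraction (default 0.25) of the signal's
  90th-percentile envelope.

The amplitude criterion is load-bearing. Band-pass filtering noise — or
ringing after a genuine oscillation stops — produces pseudo-cycles
whose durations sit exactly in the accepted range (they oscillate at
the band's center frequency), so a duration test alone cannot tell
rhythm from its absence; envelope amplitude can. When the slow rhythm
comes and goes, whole-signal estimators average the coupled stretches
together with phase-random ones and dilute; the cycle method does not.
The package computes the wavelet transform once over the whole signal
and slices it at the accepted windows, which is equivalent to a
per-window transform up to window-edge effects and far cheaper.

## Phase coherence

`phaseCoherence()` splits two simultaneously recorded channels into
consecutive time windows and a set of frequency windows; in each
(frequency, time) epoch the instantaneous phase difference
$d = P_1 - P_2$ from the two Morlet transforms is summarized as
$|\langle e^{id} \rangle|$ — 1 when the lag is perfectly consistent
(any constant lag counts), near 0 when the phases are unrelated.

The wavelet width `nCycles` sets a statistical trade-off: wavelet
smoothing correlates neighboring phase samples, so an epoch of fixed
length contains roughly `duration / (2 sigma_t)` independent samples,
and the no-coupling floor of the resultant is about
$\sqrt{\pi / (4 N_{eff})}$. The default `nCycles = 3` keeps the floor
below 0.3 for one-second windows in the 6–14 Hz range; raise `nCycles`
when frequency separation matters more than a low floor, and prefer
longer windows where the floor must be lower still.

## Time domain

The ERP logic is standard: stimulus onsets are detected on a dedicated
channel by rising-edge threshold crossing with a refractory period of
half the nominal inter-stimulus interval (an explicitly declared
paired-pulse interval is exempted), trials are cut at
`[tInitial, tFinal]` around each stimulus, and averaging attenuates
non-time-locked activity. Trials that would overrun the recording edges
are dropped, not zero-padded — padding would corrupt every spectral
quantity computed downstream.

The rectified-RMS z-score map rectifies each trial, computes RMS in
sliding windows (defaults 50 ms / 10 ms hop; the defaults are ours, not
canonical), and z-scores each trial against its own mean and SD, making
trials of different gain comparable. Z-scores are signed; an
`absolute = TRUE` option returns magnitudes for display conventions
that expect positive values.

EPSP slope is the maximum absolute first difference × `fs` within a
user window, after an optional 1 ms moving average (raw differentiation
of noisy traces is slope-unstable); ties break to the earliest time.
For the alpha-function template
$A (t/\tau) e^{1 - t/\tau}$ the maximum derivative is $A e / \tau$ at
$t = 0$, which the measurement reproduces within 1% at 10 kHz.

## Filtering and spectra

The user-facing band-pass is a direct-form Butterworth of the requested
order from `signal::butter()`, applied forward–backward (zero phase —
coupling analyses need delay-free phase estimates). Zero-phase
application squares the magnitude response, so `designBandpass()`
tabulates the *effective* squared response; each band edge then sits
near −6 dB (−3 dB per pass). Two numerical notes:

* Narrow low-frequency designs put poles close to $z = 1$; stability is
  verified on the impulse response (polynomial root finding is itself
  unreliable for clustered poles) and an unstable design is rejected
  with advice to lower the order or resample.
* The bilinear band transform preserves the analog −3 dB edges
  essentially exactly away from DC (at 30–50 Hz, fs 1000, to within
  10⁻³ dB) but warps edges very close to DC (a 4 Hz edge at fs 1000
  reads ≈ −2.5 dB); this is a property of the transform, shared by
  other implementations, not an implementation artifact.

The Welch PSD uses Hann windows, 50% overlap and mean-detrended
segments, scaled to units²/Hz so that the trapezoidal integral over
$[0, f_s/2]$ reproduces the signal variance (Parseval; the test demands
10%). The FFT panel reports one-sided *magnitude* (a unit sine peaks at
1); band power integrates the PSD trapezoidally, optionally normalized
by total power.

## Morlet scalogram

The wavelet at frequency $f$ is a complex exponential under a Gaussian
of SD $\sigma_t = n_{cycles} / (2 \pi f)$ — the standard
constant-relative-bandwidth convention; the temporal window shrinks as
frequency grows. Default `nCycles = 7`; increasing it narrows the
frequency marginal and widens the temporal one, monotonically.
Amplitude normalization makes a unit-amplitude sine yield power ≈ 1 at
its own frequency. Trial averaging averages *power*, not complex
coefficients, so induced (non-phase-locked) activity survives.
Display transforms: per-frequency z-scoring across time (`normalize`,
flattens the 1/f tilt) and decibels relative to the maximum cell
(`log`); with both requested the log is applied first — z-scoring after
log linearizes multiplicative power differences, which is what a viewer
of a normalized dB map expects. Edge samples within one wavelet
half-length (3σ) of a boundary are inside the cone of influence,
recorded in the object but deliberately not blanked.

# The synthetic generators: what they emulate, and what not

`makePacSignal()` builds
$$x(t) = g(t)\cos\theta(t) +
  \bigl[1 + d\, g(t) \cos(\theta(t) - \psi)\bigr] \sin(2\pi f_A t) +
  \varepsilon(t),$$
with $\theta(t) = 2\pi f_p t$ plus an optional Wiener phase-diffusion
term. Defaults — 8 Hz modulating 80 Hz, depth 0.7, SNR 3 (RMS ratio),
60 s at 1 kHz — are the package's standard validation conditions; a
theta-band rhythm modulating low gamma at a depth and SNR typical of
good in vivo LFP recordings. The slow carrier is a cosine so that its
Hilbert phase equals $\theta(t)$ and the amplitude profile peaks
exactly at slow phase $\psi$, making phase recovery directly testable.
The burst schedule `g(t)` gates the slow rhythm and the modulation
while the fast carrier continues unmodulated — precisely the regime in
which whole-signal estimators dilute and the cycle method is supposed
to win; a schedule that silenced the carrier as well would instead
leave a low-power pedestal that barely dilutes anything.

Two deliberate idealizations to keep in mind when reading test results:

* **Noise is white and Gaussian.** Real LFP noise is pink and partly
  oscillatory; the white choice makes analytic expectations (Parseval,
  null floors) exact but means passing tests say nothing about 1/f
  confounds such as spurious PAC from sharp-edged waveforms.
* **Strict periodicity is unrealistic in one important way.** A
  perfectly periodic fixture makes circular-shift surrogates
  *powerless*: shifting a periodic envelope by any amount only rotates
  the phase–amplitude profile, and every index here is invariant under
  profile rotation. Real slow rhythms drift, which is the property
  surrogate testing actually relies on. `phaseJitter` (rad²/s of phase
  diffusion; 5 is a moderate value giving a coherence time of a few
  rhythm cycles) exists for exactly this purpose, and the surrogate
  demonstrations use it. With jitter 0, surrogate MI equals the
  original — expected behavior, not a bug.

`makeStimRecording()` emulates a periodic (optionally paired-pulse)
stimulation protocol: rectangular pulses on a stimulus channel, an
alpha-function evoked response at fixed 20 ms latency on the signal
channel, Gaussian noise. `makeCoherentPair()` mixes a shared
band-limited source into two channels with an adjustable
shared-variance fraction and lag.

# Problem sizes used in the validation suite

Coupling properties that are about the study conditions (comodulogram
recovery, depth monotonicity, cycle-method advantage, surrogate
destruction) run at the full 60 s, fs = 1000, 13 × 19 grid; structural
unit tests use 4–30 s signals. These sizes put the whole suite at
roughly six minutes and the acceptance script at about five on one CPU.

# Known limitations

* No artifact rejection, spike detection or mini-event detection; trial
  exclusion is the user's responsibility (by `selection`).
* ABF support covers the ABF1 container (int16 with the standard
  instrument scaling chain, or float32; gap-free and episodic); ABF2
  files are recognized and rejected with a pointer to convert. The
  package never writes int16 ABF.
* The comodulogram assumes stationarity over the analyzed span; for
  rhythms that come and go, use `pacCycleBased()`.
* No statistical calibration of MI values is applied automatically;
  `pacSurrogates()` provides the null distribution, thresholds are the
  user's.
* MVL and PLV are reported per the definitions above; their known
  biases (MVL's amplitude sensitivity, PLV's saturation) are inherent
  to the estimators, not corrected.

# A worked example

```{r example, eval = FALSE}
sig <- makePacSignal(duration = 60, seed = 7)
cm <- comodulogram(sig, phaseRange = c(2, 14), ampRange = c(30, 120),
                   pStep = 1, aStep = 5)
cm
#> Comodulogram (kl_mi): 19 amp x 13 phase freqs; max 0.04362 at
#> (fp = 8 Hz, fA = 80 Hz)
prof <- pacWaveletPhasePower(sig, phaseBand = c(7, 9),
                             ampRange = c(70, 90))
binCenters(prof)[which.max(prof@meanAmplitude)]
#> [1] -0.1745329   # within one 20-degree bin of the planted phase 0
```
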