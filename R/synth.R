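#' Synthetic LFP-like signal with known phase-amplitude coupling
#'
#' Generates a slow oscillation whose phase modulates the amplitude of a
#' fast oscillation, plus white Gaussian noise - the ground truth for
#' validating every coupling estimator. The construction is
#' \deqn{x(t) = g(t) \cos\theta(t) +
#'   [1 + d\, g(t) \cos(\theta(t) - \psi)] \sin(2\pi f_A t) +
#'   \epsilon(t)}
#' with slow phase `theta(t) = 2 pi fP t` (plus optional diffusion, see
#' `phaseJitter`), modulation depth `d = depth` and coupling phase
#' `psi`. The slow carrier is a cosine so that its Hilbert phase equals
#' `theta(t)` and the fast amplitude peaks exactly at slow phase
#' `couplingPhase`. `g(t)` is 1 everywhere (stationary) or a 0/1 burst
#' schedule: inside bursts the slow rhythm is present and modulates the
#' fast carrier; outside, the carrier runs unmodulated - the regime in
#' which whole-signal estimators dilute and the cycle-based estimator
#' does not. Noise is scaled so that
#' `RMS(oscillation) / RMS(noise) = snr`.
#'
#' @param fs sampling frequency in Hz (default 1000).
#' @param duration length in seconds (default 60).
#' @param fP modulating (slow) frequency in Hz (default 8).
#' @param fA modulated (fast) frequency in Hz (default 80).
#' @param depth modulation depth in `[0, 1]` (default 0.7).
#' @param couplingPhase slow phase (radians) at which the fast amplitude
#'   is maximal (default 0).
#' @param snr linear signal-to-noise ratio (default 3); `Inf` for no
#'   noise.
#' @param bursts optional 2-column matrix of `(start, end)` seconds: the
#'   slow rhythm (and with it the modulation) exists only inside these
#'   intervals, while the fast carrier continues unmodulated - the
#'   intermittent-coupling regime the cycle-based estimator targets.
#' @param phaseJitter phase-diffusion rate of the slow rhythm in
#'   radians^2 per second (default 0: strictly periodic). A small value
#'   (e.g. 5) makes the slow phase wander as in real recordings without
#'   affecting the phase-amplitude relationship, which both rhythms
#'   inherit from the same wandering phase.
#' @param seed RNG seed; fixed seed gives identical samples.
#' @return a [ChannelSignal-class]; `meta` carries every ground-truth
#'   parameter.
#' @examples
#' sig <- makePacSignal(duration = 10, seed = 42)
#' sig@meta$fP
#' @export
makePacSignal <- function(fs = 1000, duration = 60, fP = 8, fA = 80,
                          depth = 0.7, couplingPhase = 0, snr = 3,
                          bursts = NULL, phaseJitter = 0, seed = NULL) {
  if (!(fP < fA && fA < fs / 2)) stop("need fP < fA < fs/2")
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  g <- rep(1, length(t))
  if (!is.null(bursts)) {
    bursts <- matrix(as.numeric(bursts), ncol = 2L)
    g <- rep(0, length(t))
    for (i in seq_len(nrow(bursts)))
      g[t >= bursts[i, 1L] & t < bursts[i, 2L]] <- 1
  }
  theta <- 2 * pi * fP * t
  if (phaseJitter > 0)
    theta <- theta + cumsum(stats::rnorm(length(t), 0,
                                         sqrt(phaseJitter / fs)))
  slow <- g * cos(theta)
  fast <- (1 + depth * g * cos(theta - couplingPhase)) *
    sin(2 * pi * fA * t)
  clean <- slow + fast
  noise <- if (is.finite(snr)) {
    e <- stats::rnorm(length(t))
    e * sqrt(mean(clean^2)) / (snr * sqrt(mean(e^2)))
  } else numeric(length(t))
  channelSignal(clean + noise, fs,
                meta = list(fP = fP, fA = fA, depth = depth,
                            couplingPhase = couplingPhase, snr = snr,
                            bursts = bursts, phaseJitter = phaseJitter,
                            seed = seed))
}

#' Default evoked-response template (alpha function)
#'
#' `amp * (t / tau) * exp(1 - t / tau)`: peak amplitude `amp` at
#' `t = tau`; the maximum derivative is `amp * e / tau`, attained at
#' `t = 0` - a convenient closed form for validating slope measurement.
#'
#' @param t time in seconds (vector), from 0.
#' @param tau rise time constant in seconds.
#' @param amp peak amplitude.
#' @return numeric vector of template values.
#' @export
alphaEpsp <- function(t, tau = 0.01, amp = 1) {
  stopifnot(tau > 0)
  ifelse(t < 0, 0, amp * (t / tau) * exp(1 - t / tau))
}

#' Synthetic stimulation experiment
#'
#' Two-channel [Recording-class] emulating a periodic-stimulation
#' protocol: a stimulus channel of rectangular pulses at a fixed
#' inter-stimulus interval (optionally paired pulses), and a signal
#' channel of Gaussian noise with a stereotyped evoked response inserted
#' at a fixed latency after every stimulus.
#'
#' @param fs sampling frequency in Hz (default 1000).
#' @param nTrials number of stimuli (pairs count as one trial; default
#'   10).
#' @param isi inter-stimulus interval in seconds (default 3, a standard
#'   periodic-stimulation protocol).
#' @param pairedInterval optional intra-pair interval in seconds (e.g.
#'   0.1 for a paired-pulse protocol); each stimulus becomes a pulse
#'   pair and the response is inserted after each pulse.
#' @param responseTemplate numeric vector inserted after each stimulus
#'   (default: [alphaEpsp()] with `tau` 10 ms, `amp` 2, 100 ms long).
#' @param responseLatency latency from pulse onset to template onset in
#'   seconds (default 0.02).
#' @param noiseSd standard deviation of the signal-channel noise
#'   (default 0.1; 0 for a noiseless fixture).
#' @param pulseAmp,pulseWidth stimulus pulse amplitude (default 5) and
#'   width in seconds (default 0.002).
#' @param preTime quiet time before the first stimulus in seconds
#'   (default 1).
#' @param seed RNG seed.
#' @return a [Recording-class] with channels `"signal"` and `"stim"`;
#'   `meta$stimTimes` holds the ground-truth pulse onset times and
#'   `meta$responseLatency` the inserted latency.
#' @export
makeStimRecording <- function(fs = 1000, nTrials = 10, isi = 3,
                              pairedInterval = NULL,
                              responseTemplate = NULL,
                              responseLatency = 0.02, noiseSd = 0.1,
                              pulseAmp = 5, pulseWidth = 0.002,
                              preTime = 1, seed = NULL) {
  if (is.null(responseTemplate)) {
    tt <- seq(0, 0.1, by = 1 / fs)
    responseTemplate <- alphaEpsp(tt, tau = 0.01, amp = 2)
  }
  if (isi <= length(responseTemplate) / fs)
    stop("isi must exceed the response-template duration")
  if (!is.null(seed)) set.seed(seed)
  onsets <- preTime + (seq_len(nTrials) - 1L) * isi
  if (!is.null(pairedInterval))
    onsets <- sort(c(onsets, onsets + pairedInterval))
  duration <- max(onsets) + isi
  n <- round(duration * fs)
  stim <- numeric(n)
  sigch <- if (noiseSd > 0) stats::rnorm(n, sd = noiseSd) else numeric(n)
  wPulse <- max(1L, round(pulseWidth * fs))
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    stim[i0:min(n, i0 + wPulse - 1L)] <- pulseAmp
    r0 <- i0 + round(responseLatency * fs)
    r1 <- min(n, r0 + length(responseTemplate) - 1L)
    sigch[r0:r1] <- sigch[r0:r1] + responseTemplate[seq_len(r1 - r0 + 1L)]
  }
  new("Recording",
      data = rbind(sigch, stim), fs = fs,
      channelLabels = c("signal", "stim"), units = c("mV", "V"),
      sourcePath = "",
      meta = list(stimTimes = onsets, isi = isi,
                  pairedInterval = pairedInterval,
                  responseLatency = responseLatency,
                  templateLength = length(responseTemplate),
                  noiseSd = noiseSd, seed = seed))
}

#' Synthetic coherent channel pair
#'
#' Two channels sharing a band-limited source: each channel is
#' `sqrt(coupling) * source + sqrt(1 - coupling) * ownNoise`, all
#' components band-limited to `band`, and channel 2 optionally delayed
#' by `lag`. `coupling = 1` gives identical in-band activity (phase
#' coherence ~1); `coupling = 0` gives independent channels (coherence
#' at the sampling-noise floor).
#'
#' @param fs sampling frequency in Hz.
#' @param duration length in seconds.
#' @param band shared band `c(fLow, fHigh)` in Hz, below Nyquist.
#' @param coupling shared-variance fraction in `[0, 1]`.
#' @param lag delay of channel 2 in seconds (default 0).
#' @param seed RNG seed.
#' @return list of two [ChannelSignal-class] objects of equal length
#'   and fs; ground truth in each `meta`.
#' @export
makeCoherentPair <- function(fs = 1000, duration = 30, band = c(8, 12),
                             coupling = 1, lag = 0, seed = NULL) {
  if (band[2L] >= fs / 2) stop("band must lie below Nyquist")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  spec <- bandFilterSpec(band[1L], band[2L], 4, fs)
  filt <- designButterBandpass(spec)
  bandLimited <- function() {
    x <- applyZeroPhase(stats::rnorm(n + 2L * fs), filt)
    x <- x[(fs + 1L):(fs + n)]              # drop filter edges
    x / stats::sd(x)
  }
  src <- bandLimited()
  meta <- list(band = band, coupling = coupling, lag = lag, seed = seed)
  ch1 <- sqrt(coupling) * src + sqrt(1 - coupling) * bandLimited()
  src2 <- if (lag != 0) {
    k <- round(lag * fs) %% n
    if (k > 0L) c(src[(n - k + 1L):n], src[1:(n - k)]) else src
  } else src
  ch2 <- sqrt(coupling) * src2 + sqrt(1 - coupling) * bandLimited()
  list(channelSignal(ch1, fs, meta = meta),
       channelSignal(ch2, fs, meta = meta))
}
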