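#' @import methods
NULL

#' Multichannel electrophysiology recording
#'
#' In-memory model of a digitized recording: a channels-by-samples matrix of
#' amplitudes (typically mV), one common sampling rate, and per-channel
#' labels/units. All file readers ([loadRecording()]) and the synthetic
#' generators ([makeStimRecording()]) produce this class.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling frequency in Hz.
#' @slot channelLabels character vector, one label per channel.
#' @slot units character vector, one physical-unit string per channel.
#' @slot sourcePath path of the file the recording was read from, or `""`.
#' @slot meta free-form list: sweep boundaries, ground-truth parameters of
#'   synthetic recordings, and similar provenance.
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    units = "character",
    sourcePath = "character",
    meta = "list"
  ),
  prototype(sourcePath = "", meta = list())
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains NA or non-finite values")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "one channel label per data row required")
  if (length(object@units) != nrow(object@data))
    msg <- c(msg, "one unit string per data row required")
  if (length(msg)) msg else TRUE
})

#' Single-channel signal
#'
#' A single sampled trace with its sampling rate and the time of its first
#' sample (`t0`, seconds) relative to the recording or stimulus origin.
#' This is the common currency of the spectral, time-frequency and coupling
#' functions; extract one from a [Recording-class] with [getChannel()].
#'
#' @slot samples numeric vector of amplitudes.
#' @slot fs sampling frequency in Hz.
#' @slot t0 time of the first sample in seconds.
#' @slot meta free-form list (ground truth for synthetic signals).
#'
#' @exportClass ChannelSignal
setClass("ChannelSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 meta = "list"),
  prototype(t0 = 0, meta = list())
)

setValidity("ChannelSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples contain NA or non-finite values")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Detected stimulus train
#'
#' Event times from threshold-crossing detection on a stimulation channel
#' ([detectStimuli()]).
#'
#' @slot times event times in seconds, strictly increasing.
#' @slot threshold detection threshold in amplitude units.
#' @slot isiNominal nominal inter-stimulus interval in seconds.
#'
#' @exportClass StimulusTrain
setClass("StimulusTrain",
  representation(times = "numeric", threshold = "numeric",
                 isiNominal = "numeric"))

setValidity("StimulusTrain", function(object) {
  msg <- character()
  if (length(object@times) && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Peristimulus trial matrix
#'
#' Trials-by-samples matrix time-locked to stimulus onsets, with a
#' peristimulus time axis (t = 0 at the stimulus). Built by
#' [segmentTrials()].
#'
#' @slot data numeric matrix, trials x samples.
#' @slot fs sampling frequency in Hz.
#' @slot tAxis time axis in seconds relative to the stimulus.
#' @slot trialIds original 1-based trial numbers retained after selection.
#'
#' @exportClass TrialSet
setClass("TrialSet",
  representation(data = "matrix", fs = "numeric", tAxis = "numeric",
                 trialIds = "integer"))

setValidity("TrialSet", function(object) {
  msg <- character()
  if (ncol(object@data) != length(object@tAxis))
    msg <- c(msg, "tAxis length must equal the number of samples per trial")
  if (nrow(object@data) != length(object@trialIds))
    msg <- c(msg, "one trial id per trial required")
  if (anyDuplicated(object@trialIds))
    msg <- c(msg, "trialIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Rectified-RMS z-score map
#'
#' Per-trial sliding-window RMS of the rectified signal, z-scored within
#' each trial. Rows are trials, columns are window positions.
#'
#' @slot z trials x windows matrix of z-scores (dimensionless).
#' @slot windowLen RMS window length in seconds.
#' @slot hop hop between window starts in seconds.
#' @slot tCenters window center times in seconds (peristimulus).
#'
#' @exportClass RmsZscoreMap
setClass("RmsZscoreMap",
  representation(z = "matrix", windowLen = "numeric", hop = "numeric",
                 tCenters = "numeric"))

#' Slope / latency / amplitude measures of an evoked event
#'
#' Result of [measureEvent()]: maximum absolute derivative (EPSP slope
#' convention), its time, and the peak amplitude with its time, all within
#' the analysis window.
#'
#' @slot maxSlope maximum absolute derivative, amplitude units per second.
#' @slot slopeTime time of the maximum slope in seconds.
#' @slot peakAmplitude signed amplitude of the largest-magnitude extremum.
#' @slot peakTime time of that extremum in seconds.
#' @slot window `c(tStart, tEnd)` of the analysis window in seconds.
#'
#' @exportClass EventMeasures
setClass("EventMeasures",
  representation(maxSlope = "numeric", slopeTime = "numeric",
                 peakAmplitude = "numeric", peakTime = "numeric",
                 window = "numeric"))

#' Butterworth band-pass filter specification
#'
#' @slot fLow low cutoff in Hz.
#' @slot fHigh high cutoff in Hz.
#' @slot order filter order of each cascaded section.
#' @slot fs sampling frequency in Hz.
#'
#' @exportClass BandFilterSpec
setClass("BandFilterSpec",
  representation(fLow = "numeric", fHigh = "numeric", order = "numeric",
                 fs = "numeric"))

setValidity("BandFilterSpec", function(object) {
  msg <- character()
  if (!(object@fLow > 0 && object@fLow < object@fHigh &&
        object@fHigh < object@fs / 2))
    msg <- c(msg, "need 0 < fLow < fHigh < fs/2")
  if (object@order < 1 || object@order != round(object@order))
    msg <- c(msg, "order must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Band-filtered signal with analytic envelope and phase
#'
#' Output of [filterAndDecompose()]: the zero-phase band-filtered trace,
#' its Hilbert envelope (instantaneous amplitude, >= 0) and instantaneous
#' phase in (-pi, pi].
#'
#' @slot filtered numeric vector, band-filtered signal.
#' @slot envelope numeric vector, analytic envelope.
#' @slot phase numeric vector, instantaneous phase in radians.
#' @slot fs sampling frequency in Hz.
#' @slot t0 time of first sample in seconds.
#' @slot band `c(fLow, fHigh)` of the filter in Hz.
#'
#' @exportClass AnalyticDecomposition
setClass("AnalyticDecomposition",
  representation(filtered = "numeric", envelope = "numeric",
                 phase = "numeric", fs = "numeric", t0 = "numeric",
                 band = "numeric"))

setValidity("AnalyticDecomposition", function(object) {
  msg <- character()
  n <- length(object@filtered)
  if (length(object@envelope) != n || length(object@phase) != n)
    msg <- c(msg, "filtered, envelope and phase must have equal length")
  if (any(object@envelope < 0))
    msg <- c(msg, "envelope must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' One-sided spectrum
#'
#' Either an FFT magnitude spectrum or a Welch power spectral density,
#' possibly averaged over trials.
#'
#' @slot freqs frequency axis in Hz, ascending from 0.
#' @slot power nonnegative magnitudes (kind `"fft-magnitude"`) or power
#'   densities in units^2/Hz (kind `"psd-welch"`).
#' @slot kind `"fft-magnitude"` or `"psd-welch"`.
#' @slot nAvg number of trials averaged.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(freqs = "numeric", power = "numeric", kind = "character",
                 nAvg = "integer"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power must have equal length")
  if (length(object@freqs) && (object@freqs[1] < 0 ||
      any(diff(object@freqs) <= 0)))
    msg <- c(msg, "freqs must be nonnegative ascending")
  if (any(object@power < 0))
    msg <- c(msg, "power must be nonnegative")
  if (!object@kind %in% c("fft-magnitude", "psd-welch"))
    msg <- c(msg, "unknown spectrum kind")
  if (length(msg)) msg else TRUE
})

#' Morlet wavelet scalogram
#'
#' Time-frequency power matrix from the complex Morlet transform
#' ([morletTransform()]). `transformState` records which display
#' transforms ([transformScalogram()]) have been applied.
#'
#' @slot power freqs x times matrix; nonnegative while `transformState`
#'   is `"raw"`.
#' @slot freqs analysis frequencies in Hz, ascending.
#' @slot times time axis in seconds.
#' @slot nCycles wavelet width in cycles.
#' @slot transformState one of `"raw"`, `"normalized"`, `"log"`,
#'   `"normalized+log"`.
#' @slot coi per-time half-width of the cone of influence at the lowest
#'   frequency, seconds: samples closer than this to an edge sit inside one
#'   wavelet half-length of the boundary (flagged, not blanked).
#'
#' @exportClass Scalogram
setClass("Scalogram",
  representation(power = "matrix", freqs = "numeric", times = "numeric",
                 nCycles = "numeric", transformState = "character",
                 coi = "numeric"),
  prototype(transformState = "raw", coi = numeric()))

setValidity("Scalogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freqs))
    msg <- c(msg, "one power row per frequency required")
  if (ncol(object@power) != length(object@times))
    msg <- c(msg, "one power column per time point required")
  if (object@transformState == "raw" && any(object@power < 0))
    msg <- c(msg, "raw power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Phase-binned amplitude (or power) profile with modulation index
#'
#' Mean amplitude of a fast oscillation per phase bin of a slow
#' oscillation, its normalized (sum-to-one) form, and a scalar modulation
#' index. `method` records which estimator produced it.
#'
#' @slot binEdges phase-bin edges in radians, `nBins + 1` ascending values
#'   covering (-pi, pi].
#' @slot meanAmplitude mean amplitude/power per bin, nonnegative.
#' @slot normalized `meanAmplitude / sum(meanAmplitude)`.
#' @slot mi modulation index (NA until computed).
#' @slot method one of `"kl_mi"`, `"mvl"`, `"plv"`, `"wavelet_power"`,
#'   `"cycle_power"`, or `"none"`.
#'
#' @exportClass PhaseAmplitudeProfile
setClass("PhaseAmplitudeProfile",
  representation(binEdges = "numeric", meanAmplitude = "numeric",
                 normalized = "numeric", mi = "numeric",
                 method = "character"),
  prototype(mi = NA_real_, method = "none"))

setValidity("PhaseAmplitudeProfile", function(object) {
  msg <- character()
  nb <- length(object@meanAmplitude)
  if (length(object@binEdges) != nb + 1L)
    msg <- c(msg, "need nBins + 1 bin edges")
  if (length(object@normalized) != nb)
    msg <- c(msg, "normalized must match meanAmplitude length")
  if (nb && abs(sum(object@normalized) - 1) > 1e-9)
    msg <- c(msg, "normalized must sum to 1")
  if (any(object@meanAmplitude < 0))
    msg <- c(msg, "meanAmplitude must be nonnegative")
  if (!is.na(object@mi) && object@mi < 0)
    msg <- c(msg, "mi must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Comodulogram
#'
#' Modulation-index matrix over a grid of (modulating phase frequency x
#' modulated amplitude frequency) pairs; see [comodulogram()].
#'
#' @slot mi n x m matrix of indices; rows are amplitude frequencies,
#'   columns phase frequencies.
#' @slot phaseFreqs m phase-band center frequencies in Hz.
#' @slot ampFreqs n amplitude-band center frequencies in Hz.
#' @slot pStep,aStep grid steps in Hz.
#' @slot phaseBandwidth,ampBandwidth filter bandwidths in Hz (the
#'   amplitude bandwidth reported is the minimum over the grid; it widens
#'   with the phase frequency so side-bands are retained).
#' @slot method index used per cell: `"kl_mi"`, `"mvl"` or `"plv"`.
#'
#' @exportClass Comodulogram
setClass("Comodulogram",
  representation(mi = "matrix", phaseFreqs = "numeric", ampFreqs = "numeric",
                 pStep = "numeric", aStep = "numeric",
                 phaseBandwidth = "numeric", ampBandwidth = "numeric",
                 method = "character"))

setValidity("Comodulogram", function(object) {
  msg <- character()
  if (nrow(object@mi) != length(object@ampFreqs) ||
      ncol(object@mi) != length(object@phaseFreqs))
    msg <- c(msg, "mi must be length(ampFreqs) x length(phaseFreqs)")
  if (any(object@mi < 0))
    msg <- c(msg, "mi must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Accepted cycles of a slow rhythm
#'
#' Trough-to-trough windows of the band-filtered modulating rhythm, from
#' [detectCycles()]. Windows whose duration is incompatible with the band
#' period range are rejected, which confines later coupling estimation to
#' stretches where the rhythm is actually present.
#'
#' @slot windows integer matrix with columns `start`, `end` (sample
#'   indices, inclusive), non-overlapping and ascending.
#' @slot troughTimes times of the detected troughs in seconds.
#' @slot band `c(fLow, fHigh)` of the modulating band in Hz.
#'
#' @exportClass CycleSet
setClass("CycleSet",
  representation(windows = "matrix", troughTimes = "numeric",
                 band = "numeric"))

setValidity("CycleSet", function(object) {
  msg <- character()
  w <- object@windows
  if (ncol(w) != 2L) msg <- c(msg, "windows must have two columns")
  if (nrow(w) > 1L && any(w[-1L, 1L] < w[-nrow(w), 2L]))
    msg <- c(msg, "windows must be non-overlapping and ascending")
  if (length(msg)) msg else TRUE
})

#' Phase-coherence map
#'
#' Phase-coherence value per (frequency window, time window) cell for a
#' channel pair; see [phaseCoherence()].
#'
#' @slot pc n x m matrix in `[0, 1]`; rows are frequency windows, columns
#'   time windows.
#' @slot timeWindows m x 2 matrix of `(start, end)` seconds.
#' @slot freqWindows n x 2 matrix of `(low, high)` Hz.
#'
#' @exportClass CoherenceMap
setClass("CoherenceMap",
  representation(pc = "matrix", timeWindows = "matrix",
                 freqWindows = "matrix"))

setValidity("CoherenceMap", function(object) {
  msg <- character()
  if (nrow(object@pc) != nrow(object@freqWindows) ||
      ncol(object@pc) != nrow(object@timeWindows))
    msg <- c(msg, "pc dimensions must match freqWindows x timeWindows")
  if (any(object@pc < 0 | object@pc > 1 + 1e-12))
    msg <- c(msg, "pc values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
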