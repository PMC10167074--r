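#' Sampling frequency of a signal object
#'
#' @param x a [Recording-class], [ChannelSignal-class] or
#'   [TrialSet-class].
#' @return sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "ChannelSignal", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' Number of channels of a recording
#' @param x a [Recording-class].
#' @return integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname nChannels
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' Channel labels of a recording
#' @param x a [Recording-class].
#' @return character vector of labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname channelLabels
setMethod("channelLabels", "Recording", function(x) x@channelLabels)

#' Raw data matrix / sample vector accessors
#'
#' `recordingData()` returns the channels x samples matrix of a
#' [Recording-class]; `samples()` the sample vector of a
#' [ChannelSignal-class]; `trialData()` the trials x samples matrix of a
#' [TrialSet-class].
#'
#' @param x the object.
#' @return numeric matrix or vector.
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname recordingData
setMethod("recordingData", "Recording", function(x) x@data)

#' @rdname recordingData
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname recordingData
setMethod("samples", "ChannelSignal", function(x) x@samples)

#' @rdname recordingData
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @rdname recordingData
setMethod("trialData", "TrialSet", function(x) x@data)

#' Number of trials
#' @param x a [TrialSet-class].
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname nTrials
setMethod("nTrials", "TrialSet", function(x) nrow(x@data))

#' Peristimulus time axis
#' @param x a [TrialSet-class] or [ChannelSignal-class].
#' @return numeric vector of seconds (t = 0 at the stimulus).
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname timeAxis
setMethod("timeAxis", "TrialSet", function(x) x@tAxis)
#' @rdname timeAxis
setMethod("timeAxis", "ChannelSignal", function(x)
  x@t0 + (seq_along(x@samples) - 1) / x@fs)

#' Retained trial numbers
#' @param x a [TrialSet-class].
#' @return integer vector of original 1-based trial numbers.
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @rdname trialIds
setMethod("trialIds", "TrialSet", function(x) x@trialIds)

#' Stimulus event times
#' @param x a [StimulusTrain-class].
#' @return numeric vector of seconds.
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname eventTimes
setMethod("eventTimes", "StimulusTrain", function(x) x@times)

#' Modulation index of a coupling result
#' @param x a [PhaseAmplitudeProfile-class] or [Comodulogram-class].
#' @return scalar MI for a profile; the MI matrix for a comodulogram.
#' @export
setGeneric("miValue", function(x) standardGeneric("miValue"))
#' @rdname miValue
setMethod("miValue", "PhaseAmplitudeProfile", function(x) x@mi)
#' @rdname miValue
setMethod("miValue", "Comodulogram", function(x) x@mi)

#' Phase-bin centers of a profile
#' @param x a [PhaseAmplitudeProfile-class].
#' @return bin-center phases in radians.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname binCenters
setMethod("binCenters", "PhaseAmplitudeProfile", function(x)
  (x@binEdges[-1L] + x@binEdges[-length(x@binEdges)]) / 2)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat(sprintf("  channels: %s\n",
              paste(object@channelLabels, collapse = ", ")))
  if (nzchar(object@sourcePath))
    cat(sprintf("  source: %s\n", object@sourcePath))
})

setMethod("show", "ChannelSignal", function(object) {
  cat(sprintf("ChannelSignal: %d samples @ %g Hz, t0 = %g s\n",
              length(object@samples), object@fs, object@t0))
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trial(s) x %d samples @ %g Hz, t in [%g, %g] s\n",
              nrow(object@data), ncol(object@data), object@fs,
              object@tAxis[1L], object@tAxis[length(object@tAxis)]))
})

setMethod("show", "StimulusTrain", function(object) {
  cat(sprintf("StimulusTrain: %d event(s), threshold %g, nominal ISI %g s\n",
              length(object@times), object@threshold, object@isiNominal))
})

setMethod("show", "PhaseAmplitudeProfile", function(object) {
  cat(sprintf("PhaseAmplitudeProfile: %d bins, method %s, MI = %s\n",
              length(object@meanAmplitude), object@method,
              ifelse(is.na(object@mi), "unset", format(object@mi))))
})

setMethod("show", "Comodulogram", function(object) {
  pk <- arrayInd(which.max(object@mi), dim(object@mi))
  cat(sprintf(
    "Comodulogram (%s): %d amp x %d phase freqs; max %.4g at (fp = %g Hz, fA = %g Hz)\n",
    object@method, nrow(object@mi), ncol(object@mi), max(object@mi),
    object@phaseFreqs[pk[2L]], object@ampFreqs[pk[1L]]))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf(
    "Scalogram [%s]: %d freqs (%g-%g Hz) x %d times, %g cycles\n",
    object@transformState, length(object@freqs), min(object@freqs),
    max(object@freqs), length(object@times), object@nCycles))
})

setMethod("show", "CoherenceMap", function(object) {
  cat(sprintf(
    "CoherenceMap: %d freq windows x %d time windows, mean PC = %.3f\n",
    nrow(object@pc), ncol(object@pc), mean(object@pc)))
})

setMethod("show", "CycleSet", function(object) {
  cat(sprintf("CycleSet: %d accepted cycle(s) in band %g-%g Hz\n",
              nrow(object@windows), object@band[1L], object@band[2L]))
})

setMethod("show", "EventMeasures", function(object) {
  cat(sprintf(
    "EventMeasures in [%g, %g] s: max slope %.6g at %g s; peak %.6g at %g s\n",
    object@window[1L], object@window[2L], object@maxSlope,
    object@slopeTime, object@peakAmplitude, object@peakTime))
})
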