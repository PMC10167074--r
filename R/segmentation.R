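#' Detect stimulus events on a stimulation channel
#'
#' Rising-edge threshold detection: an event is the first sample at or
#' above `threshold` following a sample below it. After an accepted
#' event, further crossings within a refractory period of
#' `0.5 * isiNominal` are suppressed, except that a paired-pulse
#' protocol can be declared via `pairedInterval`: crossings near one
#' `pairedInterval` after an accepted event are then also accepted, and
#' the refractory period restarts from the second pulse of the pair.
#'
#' @param stim stimulation channel, a [ChannelSignal-class].
#' @param threshold minimal stimulation amplitude (same units as the
#'   channel, typically mV). Values `<= 0` trigger a warning (TTL-like
#'   channels are usually positive) but are honored.
#' @param isiNominal nominal inter-stimulus interval in seconds.
#' @param pairedInterval optional intra-pair interval in seconds for
#'   paired-pulse stimulation (e.g. 0.1).
#' @return a [StimulusTrain-class] with one event time per pulse onset.
#' @examples
#' rec <- makeStimRecording(fs = 1000, nTrials = 5, isi = 1, seed = 1)
#' detectStimuli(getChannel(rec, 2), threshold = 2.5, isiNominal = 1)
#' @export
detectStimuli <- function(stim, threshold, isiNominal,
                          pairedInterval = NULL) {
  stopifnot(is(stim, "ChannelSignal"))
  if (isiNominal <= 0) stop("isiNominal must be positive")
  if (threshold <= 0)
    warning("threshold <= 0 on a stimulation channel; proceeding, but a ",
            "positive threshold between baseline and pulse amplitude is ",
            "expected")
  x <- stim@samples
  above <- x >= threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(crossings))
    stop("no threshold crossings found on the stimulation channel; ",
         "lower the threshold or check the channel index")
  tCross <- stim@t0 + (crossings - 1L) / stim@fs
  refractory <- 0.5 * isiNominal
  accepted <- tCross[1L]
  last <- tCross[1L]
  for (tc in tCross[-1L]) {
    dt <- tc - last
    ok <- dt >= refractory
    if (!ok && !is.null(pairedInterval))
      ok <- abs(dt - pairedInterval) <= max(2 / stim@fs,
                                            0.05 * pairedInterval)
    if (ok) {
      accepted <- c(accepted, tc)
      last <- tc
    }
  }
  new("StimulusTrain", times = accepted, threshold = threshold,
      isiNominal = isiNominal)
}

#' Cut peristimulus trial windows
#'
#' Extracts one trial per retained stimulus: samples from
#' `stim_time + tInitial` to `stim_time + tFinal` (stimulus time is
#' t = 0, so `tInitial` may be negative or positive). Trials whose
#' window would overrun the recording edges are dropped with a warning
#' rather than zero-padded. Passing an empty train (`train = NULL` or a
#' train with no events) returns the whole trace as a single trial
#' ("no-stim" mode).
#'
#' @param sig signal channel, a [ChannelSignal-class].
#' @param train a [StimulusTrain-class], or `NULL` for no-stim mode.
#' @param tInitial,tFinal window limits in seconds relative to the
#'   stimulus; `tInitial < tFinal`.
#' @param selection `"all"` or an integer vector of 1-based trial
#'   numbers to retain.
#' @return a [TrialSet-class]; `timeAxis()` runs from `tInitial` to
#'   `tFinal`, `trialIds()` keeps the original trial numbers.
#' @export
segmentTrials <- function(sig, train, tInitial, tFinal,
                          selection = "all") {
  stopifnot(is(sig, "ChannelSignal"))
  noStim <- is.null(train) || length(train@times) == 0L
  if (noStim) {
    n <- length(sig@samples)
    return(new("TrialSet", data = matrix(sig@samples, nrow = 1L),
               fs = sig@fs,
               tAxis = sig@t0 + (seq_len(n) - 1L) / sig@fs,
               trialIds = 1L))
  }
  if (tInitial >= tFinal)
    stop("tInitial (", tInitial, ") must be smaller than tFinal (",
         tFinal, ")")
  fs <- sig@fs
  nWin <- round((tFinal - tInitial) * fs) + 1L
  stimIdx <- round((train@times - sig@t0) * fs) + 1L
  startIdx <- stimIdx + round(tInitial * fs)
  endIdx <- startIdx + nWin - 1L
  inRange <- startIdx >= 1L & endIdx <= length(sig@samples)
  if (!all(inRange))
    warning(sum(!inRange), " trial(s) overrun the recording edges and ",
            "were dropped: ", paste(which(!inRange), collapse = ", "))
  keep <- which(inRange)
  if (!identical(selection, "all")) {
    sel <- as.integer(selection)
    bad <- setdiff(sel, seq_along(train@times))
    if (length(bad))
      stop("selection indices out of range: ", paste(bad, collapse = ", "))
    keep <- intersect(keep, sel)
  }
  if (!length(keep)) stop("no trials left after selection/edge dropping")
  data <- t(vapply(keep, function(i)
    sig@samples[startIdx[i]:endIdx[i]], numeric(nWin)))
  new("TrialSet", data = data, fs = fs,
      tAxis = tInitial + (seq_len(nWin) - 1L) / fs,
      trialIds = as.integer(keep))
}
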