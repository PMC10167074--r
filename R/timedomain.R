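#' Stimulus-locked trial average (ERP)
#'
#' Pointwise arithmetic mean across trials. Averaging time-locked trials
#' attenuates activity that is not phase-locked to the stimulus, raising
#' the signal-to-noise ratio of the evoked response by roughly
#' `sqrt(nTrials)` for independent noise.
#'
#' @param ts a [TrialSet-class] with at least one trial.
#' @return a [ChannelSignal-class]; `t0` equals the window start.
#' @export
trialAverage <- function(ts) {
  stopifnot(is(ts, "TrialSet"))
  if (nrow(ts@data) < 1L) stop("cannot average an empty TrialSet")
  channelSignal(colMeans(ts@data), ts@fs, t0 = ts@tAxis[1L])
}

#' Rectified-RMS z-score map
#'
#' Per trial: rectify (absolute value), compute the RMS in sliding
#' windows (`windowLen` long, advancing by `hop`), then z-score the RMS
#' series against its own mean and standard deviation. The result shows
#' each trial's power time course relative to that trial's mean, in
#' standard-deviation units. A trial whose RMS series is constant has no
#' scale; its row is set to zero with a warning.
#'
#' @param ts a [TrialSet-class].
#' @param windowLen RMS window length in seconds (default 50 ms).
#' @param hop window hop in seconds (default 10 ms).
#' @param absolute if `TRUE`, return `abs(z)` so the map is strictly
#'   positive; default `FALSE` (signed z-scores).
#' @return an [RmsZscoreMap-class]; rows are trials.
#' @export
rmsZscore <- function(ts, windowLen = 0.05, hop = 0.01,
                      absolute = FALSE) {
  stopifnot(is(ts, "TrialSet"))
  if (hop <= 0) stop("hop must be positive")
  fs <- ts@fs
  wl <- round(windowLen * fs)
  hp <- max(1L, round(hop * fs))
  n <- ncol(ts@data)
  if (wl > n)
    stop("windowLen (", windowLen, " s) exceeds the trial duration (",
         n / fs, " s)")
  if (wl < 1L) stop("windowLen shorter than one sample")
  starts <- seq(1L, n - wl + 1L, by = hp)
  z <- matrix(0, nrow = nrow(ts@data), ncol = length(starts))
  degenerate <- FALSE
  for (i in seq_len(nrow(ts@data))) {
    r <- abs(ts@data[i, ])
    rms <- vapply(starts, function(s)
      sqrt(mean(r[s:(s + wl - 1L)]^2)), 0)
    s <- stats::sd(rms)
    if (!is.finite(s) || s < .Machine$double.eps * max(1, mean(rms))) {
      degenerate <- TRUE
      z[i, ] <- 0
    } else {
      z[i, ] <- (rms - mean(rms)) / s
    }
  }
  if (degenerate)
    warning("constant rectified-RMS trial(s): z-score undefined, row(s) ",
            "set to zero")
  if (absolute) z <- abs(z)
  new("RmsZscoreMap", z = z, windowLen = wl / fs, hop = hp / fs,
      tCenters = ts@tAxis[starts] + (wl - 1L) / (2 * fs))
}

#' Slope, latency and amplitude of an evoked event
#'
#' Measures an event (typically an EPSP) inside a user-chosen window:
#' the maximum absolute first derivative (the standard EPSP slope
#' measure of synaptic efficacy), the time of its first occurrence, and
#' the signed peak amplitude (the extremum of largest magnitude) with
#' its time. The derivative is the first difference times `fs`, after
#' an optional moving-average smoothing; raw differentiation of noisy
#' traces is slope-unstable, so a short smoother (default 1 ms) is
#' applied first. Works identically on single trials and on trial
#' averages.
#'
#' @param sig a [ChannelSignal-class] (one trial or an average).
#' @param tStart,tEnd analysis window in seconds, inside the signal.
#' @param smoothLen moving-average length in seconds before
#'   differentiation (default 0.001; 0 disables smoothing).
#' @return an [EventMeasures-class].
#' @examples
#' t <- seq(0, 0.1, by = 1e-4)
#' epsp <- channelSignal(alphaEpsp(t, tau = 0.01, amp = 2), fs = 1e4)
#' measureEvent(epsp, 0, 0.1, smoothLen = 0)
#' @export
measureEvent <- function(sig, tStart, tEnd, smoothLen = 0.001) {
  stopifnot(is(sig, "ChannelSignal"))
  if (tStart >= tEnd) stop("tStart must be smaller than tEnd")
  fs <- sig@fs
  n <- length(sig@samples)
  i0 <- round((tStart - sig@t0) * fs) + 1L
  i1 <- round((tEnd - sig@t0) * fs) + 1L
  if (i0 < 1L || i1 > n)
    stop("measurement window [", tStart, ", ", tEnd,
         "] lies outside the signal")
  x <- sig@samples
  if (smoothLen > 0) {
    k <- max(1L, round(smoothLen * fs))
    if (k > 1L)
      x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  }
  seg <- x[i0:i1]
  valid <- which(!is.na(seg))
  deriv <- diff(x) * fs                       # deriv[i] sits between i, i+1
  dseg <- deriv[i0:(i1 - 1L)]
  dvalid <- which(!is.na(dseg))
  if (!length(dvalid)) stop("window too short to differentiate")
  iSlope <- dvalid[which.max(abs(dseg[dvalid]))]  # earliest max (which.max)
  iPeak <- valid[which.max(abs(seg[valid]))]
  new("EventMeasures",
      maxSlope = abs(dseg[iSlope]),
      slopeTime = sig@t0 + (i0 + iSlope - 1.5) / fs,  # midpoint of the diff
      peakAmplitude = seg[iPeak],
      peakTime = sig@t0 + (i0 + iPeak - 2L) / fs,
      window = c(tStart, tEnd))
}
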