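## Complex Morlet transform primitives.
##
## The wavelet at analysis frequency f is a complex exponential under a
## Gaussian whose standard deviation is sigma_t = nCycles / (2 pi f): the
## temporal window shrinks as frequency grows, which is the point of the
## scalogram over a fixed-window spectrogram. Convolution is done by
## frequency-domain multiplication after reflective padding of one
## wavelet half-length. Amplitude is normalized so a unit-amplitude sine
## at f yields power ~1 at its own row.

morletComplexOne <- function(x, fs, f, nCycles) {
  sigmaT <- nCycles / (2 * pi * f)
  half <- ceiling(3 * sigmaT * fs)
  tW <- (-half:half) / fs
  w <- exp(2i * pi * f * tW) * exp(-tW^2 / (2 * sigmaT^2))
  w <- w / (sum(Mod(w)) / 2)                      # unit sine -> envelope 1
  pad <- reflectPad(x, half)
  nConv <- length(pad$x) + length(w) - 1L
  nFft <- stats::nextn(nConv, 2L)
  conv <- stats::fft(stats::fft(c(pad$x, numeric(nFft - length(pad$x)))) *
                       stats::fft(c(w, numeric(nFft - length(w)))),
                     inverse = TRUE) / nFft
  ## center of the wavelet aligns at offset half within the padded trace
  start <- pad$npad + half + 1L
  conv[start:(start + length(x) - 1L)]
}

morletFreqGrid <- function(fLow, fHigh, nFreqs, spacing) {
  if (spacing == "log") exp(seq(log(fLow), log(fHigh), length.out = nFreqs))
  else seq(fLow, fHigh, length.out = nFreqs)
}

## Complex coefficient matrix (freqs x times); shared by the scalogram,
## the PAC estimators and phase coherence.
morletCoefficients <- function(samples, fs, freqs, nCycles) {
  out <- matrix(0 + 0i, nrow = length(freqs), ncol = length(samples))
  for (k in seq_along(freqs))
    out[k, ] <- morletComplexOne(samples, fs, freqs[k], nCycles)
  out
}

#' Morlet wavelet scalogram
#'
#' Time-frequency power of a single trace: squared modulus of the
#' convolution with complex Morlet wavelets at `nFreqs` frequencies
#' spanning `[fLow, fHigh]`. `nCycles` trades frequency resolution
#' (more cycles) against temporal resolution (fewer); the Gaussian SD
#' convention is `nCycles / (2 pi f)`.
#'
#' @param sig a [ChannelSignal-class].
#' @param fLow,fHigh frequency limits in Hz, `fHigh < fs/2`.
#' @param nFreqs number of analysis frequencies (default: 1 Hz steps).
#' @param nCycles wavelet width in cycles (default 7, minimum 3).
#' @param spacing `"linear"` (default) or `"log"` frequency spacing.
#' @return a [Scalogram-class] with `transformState = "raw"`. The `coi`
#'   slot holds the per-frequency cone-of-influence half-width (s);
#'   samples closer to an edge are attenuated by the padding but are not
#'   blanked.
#' @export
morletTransform <- function(sig, fLow, fHigh, nFreqs = NULL, nCycles = 7,
                            spacing = c("linear", "log")) {
  stopifnot(is(sig, "ChannelSignal"))
  spacing <- match.arg(spacing)
  if (!(fLow > 0 && fLow < fHigh)) stop("need 0 < fLow < fHigh")
  if (fHigh >= sig@fs / 2)
    stop("fHigh (", fHigh, " Hz) at or above Nyquist (", sig@fs / 2, " Hz)")
  if (nCycles < 3) stop("nCycles must be at least 3")
  if (is.null(nFreqs)) nFreqs <- max(2L, round(fHigh - fLow) + 1L)
  freqs <- morletFreqGrid(fLow, fHigh, nFreqs, spacing)
  coef <- morletCoefficients(sig@samples, sig@fs, freqs, nCycles)
  new("Scalogram", power = Mod(coef)^2, freqs = freqs,
      times = sig@t0 + (seq_along(sig@samples) - 1L) / sig@fs,
      nCycles = nCycles, transformState = "raw",
      coi = 3 * nCycles / (2 * pi * freqs))
}

#' Trial-averaged scalogram
#'
#' Mean of per-trial Morlet power matrices (power is averaged, not the
#' complex coefficients, so non-phase-locked power survives averaging).
#'
#' @param ts a [TrialSet-class] with at least one trial.
#' @inheritParams morletTransform
#' @return a [Scalogram-class]; `times` is the peristimulus axis.
#' @export
scalogramAverage <- function(ts, fLow, fHigh, nFreqs = NULL, nCycles = 7,
                             spacing = c("linear", "log")) {
  stopifnot(is(ts, "TrialSet"))
  if (nrow(ts@data) < 1L) stop("empty TrialSet")
  spacing <- match.arg(spacing)
  acc <- NULL
  for (i in seq_len(nrow(ts@data))) {
    sc <- morletTransform(channelSignal(ts@data[i, ], ts@fs,
                                        t0 = ts@tAxis[1L]),
                          fLow, fHigh, nFreqs, nCycles, spacing)
    acc <- if (is.null(acc)) sc@power else acc + sc@power
  }
  new("Scalogram", power = acc / nrow(ts@data), freqs = sc@freqs,
      times = ts@tAxis, nCycles = nCycles, transformState = "raw",
      coi = sc@coi)
}

#' Normalization and log display transforms of a scalogram
#'
#' `normalize` z-scores each frequency row across time (row mean 0, SD
#' 1), flattening the 1/f power gradient so weak high-frequency
#' structure becomes visible. `log` converts to decibels relative to the
#' maximum cell, `10 * log10(power / max(power))`, so the maximum maps
#' to 0 dB. When both are requested the log is applied first, then the
#' z-score. Re-applying a transform already recorded in
#' `transformState` is an error.
#'
#' @param sc a [Scalogram-class].
#' @param normalize apply the per-frequency z-score.
#' @param log apply the decibel transform.
#' @return a [Scalogram-class] with updated `transformState`.
#' @export
transformScalogram <- function(sc, normalize = FALSE, log = FALSE) {
  stopifnot(is(sc, "Scalogram"))
  if (!normalize && !log) return(sc)
  state <- strsplit(sc@transformState, "+", fixed = TRUE)[[1L]]
  if (log && "log" %in% state)
    stop("scalogram is already log-transformed")
  if (normalize && "normalized" %in% state)
    stop("scalogram is already normalized")
  p <- sc@power
  if (log) {
    mx <- max(p)
    if (mx <= 0) stop("cannot log-transform an all-zero scalogram")
    p <- 10 * log10(pmax(p, mx * 1e-12) / mx)
  }
  if (normalize) {
    p <- t(apply(p, 1L, function(r) {
      s <- stats::sd(r)
      if (s < .Machine$double.eps) rep(0, length(r))
      else (r - mean(r)) / s
    }))
  }
  newState <- paste(c(if (normalize || "normalized" %in% state)
    "normalized", if (log || "log" %in% state) "log"), collapse = "+")
  methods::initialize(sc, power = p, transformState = newState)
}
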