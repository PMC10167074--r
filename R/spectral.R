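#' Band-pass filter specification
#'
#' @param fLow,fHigh band edges in Hz, `0 < fLow < fHigh < fs/2`.
#' @param order Butterworth order of each cascaded section.
#' @param fs sampling frequency in Hz.
#' @return a [BandFilterSpec-class].
#' @export
bandFilterSpec <- function(fLow, fHigh, order, fs) {
  new("BandFilterSpec", fLow = fLow, fHigh = fHigh, order = order, fs = fs)
}

## Direct-form Butterworth band-pass of the requested order. Stability of
## narrow designs (1 Hz modulating bands at fs = 1000 put the poles close
## to z = 1) is verified empirically on the impulse response, which is
## more robust than root radii: polyroot is itself inaccurate for
## clustered poles.
designButterBandpass <- function(spec) {
  ny <- spec@fs / 2
  bt <- signal::butter(spec@order, c(spec@fLow, spec@fHigh) / ny,
                       type = "pass")
  h <- signal::filter(bt, c(1, numeric(4999L)))
  if (any(!is.finite(h)) ||
      max(abs(h[4001:5000])) > max(abs(h[1:1000])) + 1e-12)
    stop("unstable Butterworth design (order ", spec@order, ", band ",
         spec@fLow, "-", spec@fHigh, " Hz at fs ", spec@fs,
         " Hz); lower the order or resample the signal first")
  bt
}

applyZeroPhase <- function(x, filt) signal::filtfilt(filt, x)

#' Design a Butterworth band-pass and tabulate its response
#'
#' Designs the zero-phase Butterworth band-pass used by
#' [filterAndDecompose()] and returns its frequency response so the
#' realized filter can be verified against the ideal one. The filter is
#' a direct Butterworth band-pass of the stated order (-3 dB at each
#' band edge, 0 dB at the geometric mid-band, per single pass). It is
#' applied forward-backward (zero phase), which squares the magnitude
#' response; the tabulated response is this effective squared response,
#' so the band edges sit at about -6 dB there.
#'
#' @param spec a [BandFilterSpec-class].
#' @param nPoints number of response samples over `[0, fs/2]`.
#' @param at optional extra frequencies (Hz) at which the response is
#'   evaluated exactly and merged into the table (band edges, say).
#' @return a list with `filter` (the designed filter coefficients) and
#'   `response`, a data.frame with columns `freq_hz` and `gain_db`
#'   (effective zero-phase response).
#' @export
designBandpass <- function(spec, nPoints = 512L, at = NULL) {
  stopifnot(is(spec, "BandFilterSpec"))
  filt <- designButterBandpass(spec)
  w <- sort(unique(c(seq(0, pi, length.out = nPoints),
                     2 * pi * at / spec@fs)))
  evalH <- function(f, w) {
    zi <- exp(-1i * w)
    horner <- function(coef) {      # in powers of z^-1
      acc <- rep(0 + 0i, length(w))
      for (cf in rev(coef)) acc <- acc * zi + cf
      acc
    }
    horner(f$b) / horner(f$a)
  }
  gainSingle <- Mod(evalH(filt, w))
  gainDb <- 20 * log10(pmax(gainSingle^2, 1e-300))  # forward-backward
  list(filter = filt,
       response = data.frame(freq_hz = w / pi * spec@fs / 2,
                             gain_db = gainDb))
}

#' Zero-phase band filtering with analytic envelope and phase
#'
#' Band-filters the signal with the cascade from [designBandpass()]
#' applied forward-backward (no group delay, so instantaneous phase is
#' usable for coupling analysis), then computes the Hilbert analytic
#' signal to obtain the instantaneous envelope and phase. Edge effects
#' of both the filter and the Hilbert transform are mitigated by
#' reflective padding (three filter lengths), trimmed before returning.
#'
#' @param sig a [ChannelSignal-class].
#' @param spec a [BandFilterSpec-class] with `fs == samplingRate(sig)`.
#' @return an [AnalyticDecomposition-class].
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' sig <- channelSignal(sin(2 * pi * 10 * t), fs = 1000)
#' d <- filterAndDecompose(sig, bandFilterSpec(8, 12, 4, 1000))
#' @export
filterAndDecompose <- function(sig, spec) {
  stopifnot(is(sig, "ChannelSignal"), is(spec, "BandFilterSpec"))
  if (!isTRUE(all.equal(sig@fs, spec@fs)))
    stop("filter spec fs (", spec@fs, ") does not match the signal fs (",
         sig@fs, ")")
  filt <- designButterBandpass(spec)
  nFilt <- length(filt$a)
  if (length(sig@samples) <= 3L * nFilt)
    stop("signal too short (", length(sig@samples),
         " samples) for order-", spec@order, " filtering")
  ## pad enough to absorb both filter transients and slow-band Hilbert edges
  npad <- max(3L * nFilt, ceiling(3 * spec@fs / spec@fLow))
  padded <- reflectPad(sig@samples, npad)
  y <- applyZeroPhase(padded$x, filt)
  analytic <- hilbertAnalytic(y)
  idx <- (padded$npad + 1L):(padded$npad + length(sig@samples))
  new("AnalyticDecomposition",
      filtered = y[idx],
      envelope = Mod(analytic[idx]),
      phase = wrapPhase(Arg(analytic[idx])),
      fs = sig@fs, t0 = sig@t0, band = c(spec@fLow, spec@fHigh))
}

oneSidedFreqs <- function(n, fs) (seq_len(n %/% 2 + 1L) - 1L) * fs / n

fftMagnitudeOne <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- n %/% 2 + 1L
  mag <- Mod(X[seq_len(half)]) / n
  scale <- rep(2, half)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[half] <- 1
  mag * scale
}

#' One-sided FFT magnitude spectrum
#'
#' Magnitude spectrum of a single trace, or the arithmetic mean of
#' per-trial magnitude spectra of a [TrialSet-class]. Scaled so a unit
#' sine yields a peak magnitude of ~1 at its frequency.
#'
#' @param x a [ChannelSignal-class] or [TrialSet-class].
#' @param average for a TrialSet: `TRUE` averages per-trial spectra,
#'   `FALSE` uses the first trial only.
#' @return a [Spectrum-class] with `kind = "fft-magnitude"`.
#' @export
fftSpectrum <- function(x, average = TRUE) {
  if (is(x, "ChannelSignal")) {
    mat <- matrix(x@samples, nrow = 1L)
    fs <- x@fs
  } else if (is(x, "TrialSet")) {
    mat <- if (average) x@data else x@data[1L, , drop = FALSE]
    fs <- x@fs
  } else stop("x must be a ChannelSignal or TrialSet")
  if (!nrow(mat) || !ncol(mat)) stop("empty input")
  specs <- t(apply(mat, 1L, fftMagnitudeOne, fs = fs))
  new("Spectrum", freqs = oneSidedFreqs(ncol(mat), fs),
      power = colMeans(specs), kind = "fft-magnitude",
      nAvg = nrow(mat))
}

## One-sided Welch PSD of one trace (Hann window, units^2/Hz).
welchOne <- function(x, fs, segSamples, overlap) {
  step <- max(1L, round(segSamples * (1 - overlap)))
  starts <- seq(1L, length(x) - segSamples + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segSamples) - 1L) /
                         (segSamples - 1L))
  u <- sum(w^2)
  half <- segSamples %/% 2 + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + segSamples - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[seq_len(half)])^2 / (fs * u)
    P[2:(half - 1L)] <- 2 * P[2:(half - 1L)]
    if (segSamples %% 2L != 0L) P[half] <- 2 * P[half]
    acc <- acc + P
  }
  acc / length(starts)
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD (Hann window, mean-detrended segments) in
#' units^2/Hz. For a [TrialSet-class] with `average = TRUE`, per-trial
#' PSDs are averaged.
#'
#' @param x a [ChannelSignal-class] or [TrialSet-class].
#' @param segLen segment length in seconds (default: 1/8 of the trace,
#'   the classic eight-segment split).
#' @param overlap fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @param average average per-trial PSDs (TrialSet input only).
#' @return a [Spectrum-class] with `kind = "psd-welch"`. The trapezoidal
#'   integral of `power` over `[0, fs/2]` approximates the signal
#'   variance (Parseval).
#' @export
welchPsd <- function(x, segLen = NULL, overlap = 0.5, average = TRUE) {
  if (is(x, "ChannelSignal")) {
    mat <- matrix(x@samples, nrow = 1L)
    fs <- x@fs
  } else if (is(x, "TrialSet")) {
    mat <- if (average) x@data else x@data[1L, , drop = FALSE]
    fs <- x@fs
  } else stop("x must be a ChannelSignal or TrialSet")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  n <- ncol(mat)
  segSamples <- if (is.null(segLen)) max(8L, n %/% 8L)
                else round(segLen * fs)
  if (segSamples > n)
    stop("segLen (", segSamples / fs, " s) exceeds the trace duration (",
         n / fs, " s)")
  if (segSamples < 8L) stop("segment too short for a meaningful PSD")
  psds <- t(apply(mat, 1L, welchOne, fs = fs, segSamples = segSamples,
                  overlap = overlap))
  new("Spectrum", freqs = oneSidedFreqs(segSamples, fs),
      power = colMeans(psds), kind = "psd-welch", nAvg = nrow(mat))
}

#' Band power of a spectrum
#'
#' Trapezoidal integral of spectral power over `[fLow, fHigh]`;
#' `relative = TRUE` divides by the integral over the full spectrum
#' range, giving a fraction in `[0, 1]`.
#'
#' @param sp a [Spectrum-class] (PSD input is the standard use; FFT
#'   magnitude is integrated as-is).
#' @param fLow,fHigh band limits in Hz, inside the spectrum range.
#' @param relative return the band fraction of total power.
#' @return scalar band power (units^2 for a PSD) or fraction.
#' @export
bandPower <- function(sp, fLow, fHigh, relative = FALSE) {
  stopifnot(is(sp, "Spectrum"))
  if (fLow >= fHigh) stop("fLow must be smaller than fHigh")
  rng <- range(sp@freqs)
  if (fLow < rng[1L] - 1e-9 || fHigh > rng[2L] + 1e-9)
    stop("band [", fLow, ", ", fHigh, "] outside the spectrum range [",
         rng[1L], ", ", rng[2L], "]")
  grid <- sort(unique(c(sp@freqs[sp@freqs >= fLow & sp@freqs <= fHigh],
                        fLow, fHigh)))
  p <- stats::approx(sp@freqs, sp@power, xout = grid, rule = 2)$y
  num <- pracma::trapz(grid, p)
  if (!relative) return(num)
  num / pracma::trapz(sp@freqs, sp@power)
}
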