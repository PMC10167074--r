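#' Construct a single-channel signal
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling frequency in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @param meta optional list of metadata.
#' @return a [ChannelSignal-class].
#' @export
channelSignal <- function(samples, fs, t0 = 0, meta = list()) {
  new("ChannelSignal", samples = as.numeric(samples), fs = fs, t0 = t0,
      meta = meta)
}

## Analytic signal via the FFT half-spectrum construction: zero out the
## negative frequencies, double the positive ones, keep DC and Nyquist.
hilbertAnalytic <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for an analytic decomposition")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Wrap angles into (-pi, pi].
wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

## Circular distance between two angles, in [0, pi].
circDist <- function(a, b) {
  d <- abs(wrapPhase(a - b))
  d
}

## Reflective (mirror) padding of a vector by npad samples on each side.
reflectPad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad <= 0L) return(list(x = x, npad = 0L))
  list(x = c(rev(x[2:(npad + 1L)]), x, rev(x[(n - npad):(n - 1L)])),
       npad = as.integer(npad))
}

## Coerce a user argument to ChannelSignal; numeric vectors need fs.
asChannelSignal <- function(x, fs = NULL) {
  if (methods::is(x, "ChannelSignal")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs)) stop("a numeric signal needs an explicit 'fs'")
    return(channelSignal(x, fs))
  }
  stop("cannot interpret input as a single-channel signal")
}

## Mean of complex exponentials -> resultant length (plain Rayleigh R).
resultantLength <- function(phi) Mod(mean(exp(1i * phi)))

## Zero-phase band extraction in the frequency domain: unit gain inside
## [fLow, fHigh], raised-cosine roll-off over `transition` Hz on each
## side, zero beyond. Reflective padding absorbs the circular wrap.
## Returns the analytic decomposition directly (the one-sided spectrum
## IS the analytic signal). Used where skirt steepness matters more
## than a realizable filter: the comodulogram's band separation.
fftBandDecompose <- function(sig, fLow, fHigh, transition = 1) {
  fs <- sig@fs
  n <- length(sig@samples)
  npad <- min(n - 1L, ceiling(3 * fs / fLow))
  pad <- reflectPad(sig@samples, npad)
  m <- length(pad$x)
  X <- stats::fft(pad$x)
  f <- (seq_len(m) - 1L) * fs / m
  f[f > fs / 2] <- f[f > fs / 2] - fs            # signed frequencies
  af <- abs(f)
  gain <- numeric(m)
  inside <- af >= fLow & af <= fHigh
  gain[inside] <- 1
  lo <- af >= fLow - transition & af < fLow
  gain[lo] <- 0.5 * (1 + cos(pi * (fLow - af[lo]) / transition))
  hi <- af > fHigh & af <= fHigh + transition
  gain[hi] <- 0.5 * (1 + cos(pi * (af[hi] - fHigh) / transition))
  ## analytic: keep positive frequencies doubled, kill negative
  h <- numeric(m)
  h[f > 0] <- 2
  h[f == 0] <- 1
  analytic <- stats::fft(X * gain * h, inverse = TRUE) / m
  idx <- (pad$npad + 1L):(pad$npad + n)
  a <- analytic[idx]
  new("AnalyticDecomposition", filtered = Re(a), envelope = Mod(a),
      phase = wrapPhase(Arg(a)), fs = fs, t0 = sig@t0,
      band = c(fLow, fHigh))
}
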