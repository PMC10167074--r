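#' Mean amplitude per phase bin
#'
#' Bins the instantaneous phase of the slow (modulating) oscillation
#' into `nBins` equal bins over (-pi, pi] and averages the fast
#' oscillation's amplitude within each bin - the composite
#' phase-amplitude distribution that all modulation indices start from.
#'
#' @param phase phases in radians (any real values; wrapped internally).
#' @param amplitude nonnegative amplitudes, same length as `phase`.
#' @param nBins number of phase bins (default 18, i.e. 20 degrees).
#' @return a [PhaseAmplitudeProfile-class] with `mi` unset.
#' @export
phaseAmplitudeProfile <- function(phase, amplitude, nBins = 18L) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude must have equal length")
  if (nBins < 4L) stop("need at least 4 phase bins")
  if (any(amplitude < 0)) stop("amplitude must be nonnegative")
  phi <- wrapPhase(phase)
  edges <- seq(-pi, pi, length.out = nBins + 1L)
  bin <- findInterval(phi, edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  bin[bin == 0L] <- 1L                     # phi == -pi folds into bin 1
  counts <- tabulate(bin, nbins = nBins)
  if (any(counts == 0L))
    stop(sum(counts == 0L), " empty phase bin(s): use a longer signal ",
         "or fewer bins")
  meanAmp <- as.numeric(tapply(amplitude, factor(bin, levels = seq_len(nBins)),
                               mean))
  tot <- sum(meanAmp)
  if (tot <= 0) stop("total amplitude is zero; nothing to normalize")
  new("PhaseAmplitudeProfile", binEdges = edges, meanAmplitude = meanAmp,
      normalized = meanAmp / tot, mi = NA_real_, method = "none")
}

klFromNormalized <- function(p) {
  n <- length(p)
  nz <- p[p > 0]
  H <- -sum(nz * log(nz))
  (log(n) - H) / log(n)
}

#' Modulation index of a phase-amplitude relationship
#'
#' Three estimators of phase-amplitude coupling strength:
#' \describe{
#'   \item{`kl_mi`}{Kullback-Leibler modulation index of a phase-binned
#'     amplitude profile: `(log N - H(p)) / log N` with `H` the Shannon
#'     entropy of the normalized profile. 0 for a uniform profile, 1 for
#'     all mass in one bin.}
#'   \item{`mvl`}{mean vector length, `|mean(A * exp(1i * phi))| /
#'     mean(A)` - the amplitude-weighted resultant, normalized by the
#'     mean amplitude so it is dimensionless and scale-free.}
#'   \item{`plv`}{phase-locking value between the slow phase and the
#'     phase of the amplitude envelope's own fluctuation in the
#'     modulating band: `|mean(exp(1i * (phi - phiA)))|`. Requires `fs`
#'     and `phaseBand` to extract `phiA` from the envelope.}
#' }
#'
#' @param x a [PhaseAmplitudeProfile-class] (then `kl_mi` is computed
#'   from it) or a numeric phase vector in radians.
#' @param amplitude amplitude vector (needed when `x` is a phase
#'   vector).
#' @param method `"kl_mi"`, `"mvl"` or `"plv"`.
#' @param nBins phase bins used when `kl_mi` is computed from raw
#'   series.
#' @param fs,phaseBand sampling rate (Hz) and modulating band
#'   `c(fLow, fHigh)` (Hz); required by `"plv"` only.
#' @param filterOrder Butterworth section order for the envelope filter
#'   (`"plv"`).
#' @return scalar index, `>= 0` (`kl_mi` and `plv` are `<= 1`).
#' @examples
#' modulationIndex(phaseAmplitudeProfile(runif(2000, -pi, pi),
#'                                       rep(1, 2000)))
#' @export
modulationIndex <- function(x, amplitude = NULL,
                            method = c("kl_mi", "mvl", "plv"),
                            nBins = 18L, fs = NULL, phaseBand = NULL,
                            filterOrder = 2L) {
  method <- match.arg(method)
  if (is(x, "PhaseAmplitudeProfile")) {
    if (method != "kl_mi")
      stop("a profile carries binned amplitudes only; '", method,
           "' needs the raw phase and amplitude series")
    return(klFromNormalized(x@normalized))
  }
  phase <- as.numeric(x)
  if (is.null(amplitude))
    stop("raw-series methods need both phase and amplitude")
  if (length(phase) != length(amplitude))
    stop("phase and amplitude must have equal length")
  if (sum(amplitude) <= 0) stop("total amplitude is zero")
  switch(method,
    kl_mi = klFromNormalized(
      phaseAmplitudeProfile(phase, amplitude, nBins)@normalized),
    mvl = Mod(mean(amplitude * exp(1i * phase))) / mean(amplitude),
    plv = {
      if (is.null(fs) || is.null(phaseBand))
        stop("plv needs fs and phaseBand to band-filter the envelope")
      envSig <- channelSignal(amplitude - mean(amplitude), fs)
      spec <- bandFilterSpec(phaseBand[1L], phaseBand[2L], filterOrder, fs)
      phiA <- filterAndDecompose(envSig, spec)@phase
      resultantLength(phase - phiA)
    })
}

#' Comodulogram over a (phase frequency x amplitude frequency) grid
#'
#' For each pair of a narrow modulating band (center `fp`, bandwidth
#' `pStep`) and a broad modulated band (center `fA`, bandwidth
#' `max(aStep, 2 * fp)` so the modulation side-bands `fA +/- fp` are
#' retained), the raw signal(s) are band-filtered, the Hilbert transform
#' yields the modulating phase and modulated amplitude, and the chosen
#' index is computed. Single-channel coupling passes the same signal as
#' `sigPhase` and `sigAmp`; two-channel coupling passes the modulating
#' and modulated channels separately.
#'
#' Band extraction here uses a zero-phase frequency-domain filter with
#' raised-cosine roll-off rather than the user-facing Butterworth of
#' [filterAndDecompose()]: comodulogram cells compete on the relative
#' modulation of their envelopes, and with gentle IIR skirts a cell
#' whose passband attenuates the carrier toward side-band amplitude
#' shows inflated relative modulation, drifting the peak off the true
#' amplitude frequency. Steep skirts keep each cell's content to its
#' own band.
#'
#' @param sigPhase,sigAmp [ChannelSignal-class] objects of equal
#'   sampling rate (`sigAmp` defaults to `sigPhase`: single-channel
#'   mode).
#' @param phaseRange,ampRange `c(low, high)` center-frequency ranges in
#'   Hz for the modulating and modulated grids.
#' @param pStep,aStep grid steps in Hz.
#' @param nBins phase bins for the KL index.
#' @param method per-cell index: `"kl_mi"` (default), `"mvl"` or
#'   `"plv"`.
#' @return a [Comodulogram-class] (`miValue()` gives the matrix, rows =
#'   amplitude frequencies, columns = phase frequencies).
#' @examples
#' \donttest{
#' sig <- makePacSignal(duration = 20, seed = 1)
#' cm <- comodulogram(sig, phaseRange = c(4, 12), ampRange = c(60, 100),
#'                    pStep = 2, aStep = 10)
#' }
#' @export
comodulogram <- function(sigPhase, sigAmp = sigPhase,
                         phaseRange, ampRange, pStep = 1, aStep = 5,
                         nBins = 18L,
                         method = c("kl_mi", "mvl", "plv")) {
  method <- match.arg(method)
  stopifnot(is(sigPhase, "ChannelSignal"), is(sigAmp, "ChannelSignal"))
  if (!isTRUE(all.equal(sigPhase@fs, sigAmp@fs)))
    stop("both channels must share one sampling rate")
  fs <- sigPhase@fs
  pf <- seq(phaseRange[1L], phaseRange[2L], by = pStep)
  af <- seq(ampRange[1L], ampRange[2L], by = aStep)
  if (max(af) <= max(pf))
    warning("modulated (amplitude) band does not exceed the modulating ",
            "(phase) band; physiologically inverted, computing anyway")
  mi <- matrix(0, nrow = length(af), ncol = length(pf))
  ny <- fs / 2
  for (j in seq_along(pf)) {
    fp <- pf[j]
    phaseBand <- c(max(fp - pStep / 2, 0.05), fp + pStep / 2)
    dp <- fftBandDecompose(sigPhase, phaseBand[1L], phaseBand[2L],
                           transition = pStep / 2)
    for (k in seq_along(af)) {
      fa <- af[k]
      bw <- max(aStep, 2 * fp)
      ampBand <- c(max(fa - bw / 2, phaseBand[2L] + 0.5),
                   min(fa + bw / 2, ny * 0.98))
      da <- fftBandDecompose(sigAmp, ampBand[1L], ampBand[2L],
                             transition = pStep)
      mi[k, j] <- switch(method,
        kl_mi = klFromNormalized(
          phaseAmplitudeProfile(dp@phase, da@envelope, nBins)@normalized),
        mvl = Mod(mean(da@envelope * exp(1i * dp@phase))) /
          mean(da@envelope),
        plv = {
          envSig <- channelSignal(da@envelope - mean(da@envelope), fs)
          phiA <- fftBandDecompose(envSig, phaseBand[1L], phaseBand[2L],
                                   transition = pStep / 2)@phase
          resultantLength(dp@phase - phiA)
        })
    }
  }
  new("Comodulogram", mi = mi, phaseFreqs = pf, ampFreqs = af,
      pStep = pStep, aStep = aStep, phaseBandwidth = pStep,
      ampBandwidth = max(aStep, 2 * min(pf)), method = method)
}

#' Wavelet phase-binned power profile
#'
#' Phase-amplitude coupling for one pair of bands: the modulating phase
#' comes from the Hilbert transform of the band-filtered `sigPhase`;
#' the modulated power from a Morlet transform of `sigAmp` over
#' `ampRange`, averaged across the band's frequencies. The mean power
#' per phase bin is the profile; its KL modulation index is stored in
#' `mi`. With a [TrialSet-class] in `perTrial`, one profile is computed
#' per trial and the bin-wise average is returned.
#'
#' @param sigPhase,sigAmp [ChannelSignal-class] objects (equal fs);
#'   `sigAmp` defaults to `sigPhase`.
#' @param phaseBand modulating band `c(fLow, fHigh)` in Hz.
#' @param ampRange modulated band `c(fLow, fHigh)` in Hz.
#' @param nBins phase bins.
#' @param nCycles Morlet width in cycles.
#' @param perTrial optional [TrialSet-class] (same channel, segmented):
#'   profiles are computed per trial and averaged.
#' @param filterOrder Butterworth section order for the phase filter.
#' @return a [PhaseAmplitudeProfile-class], `method = "wavelet_power"`.
#' @export
pacWaveletPhasePower <- function(sigPhase, sigAmp = sigPhase, phaseBand,
                                 ampRange, nBins = 18L, nCycles = 7,
                                 perTrial = NULL, filterOrder = 2L) {
  if (!is.null(perTrial)) {
    stopifnot(is(perTrial, "TrialSet"))
    acc <- NULL
    for (i in seq_len(nrow(perTrial@data))) {
      tr <- channelSignal(perTrial@data[i, ], perTrial@fs)
      p <- pacWaveletPhasePower(tr, tr, phaseBand, ampRange, nBins,
                                nCycles, NULL, filterOrder)
      acc <- if (is.null(acc)) p@meanAmplitude
             else acc + p@meanAmplitude
    }
    meanAmp <- acc / nrow(perTrial@data)
    norm <- meanAmp / sum(meanAmp)
    return(new("PhaseAmplitudeProfile", binEdges = p@binEdges,
               meanAmplitude = meanAmp, normalized = norm,
               mi = klFromNormalized(norm), method = "wavelet_power"))
  }
  stopifnot(is(sigPhase, "ChannelSignal"), is(sigAmp, "ChannelSignal"))
  if (!isTRUE(all.equal(sigPhase@fs, sigAmp@fs)))
    stop("both channels must share one sampling rate")
  dp <- filterAndDecompose(sigPhase,
          bandFilterSpec(phaseBand[1L], phaseBand[2L], filterOrder,
                         sigPhase@fs))
  sc <- morletTransform(sigAmp, ampRange[1L], ampRange[2L],
                        nCycles = nCycles)
  bandPow <- colMeans(sc@power)            # mean over amp frequencies
  prof <- phaseAmplitudeProfile(dp@phase, bandPow, nBins)
  methods::initialize(prof, mi = klFromNormalized(prof@normalized),
                      method = "wavelet_power")
}

#' Detect cycles of the modulating rhythm
#'
#' Finds local minima (troughs) of the band-filtered trace and forms
#' trough-to-trough windows, one per candidate cycle. A window is
#' accepted only if (a) its duration is compatible with the band, within
#' 25% of the period range `[1/fHigh, 1/fLow]`, and (b) the rhythm is
#' actually present there: the mean analytic envelope inside the window
#' must reach `minAmplitude` times the signal's 90th-percentile
#' envelope. The amplitude criterion is what rejects stretches where
#' the band contains only filtered noise or filter ringing, whose
#' pseudo-cycles have plausible durations.
#'
#' @param decomp an [AnalyticDecomposition-class] produced with `band`.
#' @param band the modulating band `c(fLow, fHigh)` in Hz.
#' @param minAmplitude envelope acceptance fraction (default 0.25).
#' @return a [CycleSet-class] of accepted windows.
#' @export
detectCycles <- function(decomp, band, minAmplitude = 0.25) {
  stopifnot(is(decomp, "AnalyticDecomposition"))
  if (!isTRUE(all.equal(as.numeric(decomp@band), as.numeric(band))))
    stop("decomposition was produced with band ",
         paste(decomp@band, collapse = "-"), " Hz, not ",
         paste(band, collapse = "-"), " Hz")
  fs <- decomp@fs
  fLow <- band[1L]; fHigh <- band[2L]
  minDist <- max(1L, round(0.5 / fHigh * fs))
  pk <- pracma::findpeaks(-decomp@filtered, minpeakdistance = minDist)
  if (is.null(pk) || nrow(pk) < 2L)
    stop("fewer than 2 troughs found in the ", fLow, "-", fHigh,
         " Hz band")
  troughs <- sort(pk[, 2L])
  dur <- diff(troughs) / fs
  okDur <- dur >= 0.75 / fHigh & dur <= 1.25 / fLow
  envRef <- stats::quantile(decomp@envelope, 0.9, names = FALSE)
  starts <- troughs[-length(troughs)]
  ends <- troughs[-1L]
  okAmp <- vapply(seq_along(starts), function(i)
    mean(decomp@envelope[starts[i]:ends[i]]) >= minAmplitude * envRef,
    logical(1L))
  keep <- which(okDur & okAmp)
  windows <- cbind(start = starts[keep], end = ends[keep])
  ## trough-to-trough windows share endpoints; trim starts by one sample
  ## where needed so windows are strictly non-overlapping
  if (nrow(windows) > 1L) {
    ov <- which(windows[-1L, 1L] <= windows[-nrow(windows), 2L]) + 1L
    windows[ov, 1L] <- windows[ov, 1L] + 1L
  }
  new("CycleSet", windows = windows,
      troughTimes = decomp@t0 + (troughs - 1L) / fs,
      band = c(fLow, fHigh))
}

#' Cycle-based phase-amplitude coupling
#'
#' The cycle-detection PAC estimator: the modulating channel is
#' band-filtered and its individual cycles are detected
#' ([detectCycles()]); Morlet power of the raw modulated channel
#' (averaged over `ampRange`) and Hilbert phase of the modulating band
#' are then collected only inside the accepted cycle windows and binned
#' by phase. Because estimation is confined to epochs where the slow
#' rhythm is genuinely present, this estimator keeps its sensitivity
#' when the modulating oscillation comes and goes, where whole-signal
#' estimators dilute the coupling with phase-random stretches.
#'
#' @inheritParams pacWaveletPhasePower
#' @param minAmplitude passed to [detectCycles()].
#' @return a [PhaseAmplitudeProfile-class], `method = "cycle_power"`,
#'   with the number of accepted cycles in `attr(,"nCyclesUsed")`.
#' @export
pacCycleBased <- function(sigPhase, sigAmp = sigPhase, phaseBand,
                          ampRange, nBins = 18L, nCycles = 7,
                          filterOrder = 2L, minAmplitude = 0.25) {
  stopifnot(is(sigPhase, "ChannelSignal"), is(sigAmp, "ChannelSignal"))
  if (!isTRUE(all.equal(sigPhase@fs, sigAmp@fs)))
    stop("both channels must share one sampling rate")
  dp <- filterAndDecompose(sigPhase,
          bandFilterSpec(phaseBand[1L], phaseBand[2L], filterOrder,
                         sigPhase@fs))
  cyc <- detectCycles(dp, phaseBand, minAmplitude)
  if (nrow(cyc@windows) < 5L)
    stop("only ", nrow(cyc@windows), " accepted cycle(s); at least 5 ",
         "are required for a cycle-based estimate")
  sc <- morletTransform(sigAmp, ampRange[1L], ampRange[2L],
                        nCycles = nCycles)
  bandPow <- colMeans(sc@power)
  idx <- unlist(lapply(seq_len(nrow(cyc@windows)), function(i)
    cyc@windows[i, 1L]:cyc@windows[i, 2L]))
  prof <- phaseAmplitudeProfile(dp@phase[idx], bandPow[idx], nBins)
  prof <- methods::initialize(prof,
                              mi = klFromNormalized(prof@normalized),
                              method = "cycle_power")
  attr(prof, "nCyclesUsed") <- nrow(cyc@windows)
  prof
}

#' Two-channel phase coherence
#'
#' Splits the common time span into consecutive windows of `wdTime`
#' seconds and the `[fLow, fHigh]` range into `nFreqWindows` frequency
#' windows. Morlet transforms of both channels provide instantaneous
#' phases; within each (frequency window, time window) epoch the
#' distribution of the phase difference `d = P1 - P2` over all
#' time-frequency samples is summarized by `pc = |mean(exp(1i * d))|`:
#' 1 when the phase lag is perfectly consistent (including any constant
#' lag), near 0 when the phases are unrelated.
#'
#' @param sig1,sig2 [ChannelSignal-class] objects, equal length and fs.
#' @param wdTime time-window length in seconds (`>= 2 / fLow`).
#' @param fLow,fHigh frequency range in Hz.
#' @param nFreqWindows number of frequency windows.
#' @param nCycles Morlet width in cycles (default 3: short wavelets
#'   maximize the number of temporally independent phase samples per
#'   epoch, keeping the no-coupling floor low; raise for sharper
#'   frequency separation).
#' @return a [CoherenceMap-class] (`n x m`: frequency windows x time
#'   windows).
#' @export
phaseCoherence <- function(sig1, sig2, wdTime, fLow, fHigh,
                           nFreqWindows = 4L, nCycles = 3) {
  stopifnot(is(sig1, "ChannelSignal"), is(sig2, "ChannelSignal"))
  if (length(sig1@samples) != length(sig2@samples))
    stop("channels differ in length (", length(sig1@samples), " vs ",
         length(sig2@samples), " samples)")
  if (!isTRUE(all.equal(sig1@fs, sig2@fs)))
    stop("channels differ in sampling rate")
  fs <- sig1@fs
  if (wdTime < 2 / fLow)
    stop("wdTime must cover at least two cycles of fLow (>= ",
         2 / fLow, " s)")
  n <- length(sig1@samples)
  wdSamples <- round(wdTime * fs)
  m <- n %/% wdSamples
  if (m < 1L) stop("signal shorter than one time window")
  fEdges <- seq(fLow, fHigh, length.out = nFreqWindows + 1L)
  ## a few analysis frequencies per window, at least 2
  perWin <- max(2L, ceiling((fHigh - fLow) / nFreqWindows))
  freqs <- unlist(lapply(seq_len(nFreqWindows), function(k)
    seq(fEdges[k], fEdges[k + 1L], length.out = perWin + 1L)[-1L]))
  winOf <- rep(seq_len(nFreqWindows), each = perWin)
  c1 <- morletCoefficients(sig1@samples, fs, freqs, nCycles)
  c2 <- morletCoefficients(sig2@samples, fs, freqs, nCycles)
  expD <- exp(1i * (Arg(c1) - Arg(c2)))
  pc <- matrix(0, nrow = nFreqWindows, ncol = m)
  for (j in seq_len(m)) {
    cols <- ((j - 1L) * wdSamples + 1L):(j * wdSamples)
    for (k in seq_len(nFreqWindows))
      pc[k, j] <- Mod(mean(expD[winOf == k, cols]))
  }
  tw <- cbind(start = (seq_len(m) - 1L) * wdTime + sig1@t0,
              end = seq_len(m) * wdTime + sig1@t0)
  fw <- cbind(low = fEdges[-length(fEdges)], high = fEdges[-1L])
  new("CoherenceMap", pc = pmin(pc, 1), timeWindows = tw,
      freqWindows = fw)
}

#' Circularly shift a signal in time
#'
#' Rotates the sample vector by `shift` seconds (samples wrap around).
#' The standard surrogate for coupling analyses: shifting the amplitude
#' channel relative to the phase channel destroys any genuine
#' phase-amplitude relationship while preserving both marginal spectra.
#'
#' @param sig a [ChannelSignal-class].
#' @param shift shift in seconds (positive delays the signal).
#' @return the shifted [ChannelSignal-class].
#' @export
circularShift <- function(sig, shift) {
  stopifnot(is(sig, "ChannelSignal"))
  n <- length(sig@samples)
  k <- round(shift * sig@fs) %% n
  if (k == 0L) return(sig)
  methods::initialize(sig, samples = c(sig@samples[(n - k + 1L):n],
                                       sig@samples[1:(n - k)]))
}

#' Surrogate distribution of the modulation index
#'
#' Computes the KL modulation index for `n` circularly shifted copies of
#' the amplitude channel (shift drawn uniformly between `minShift` and
#' the signal duration minus `minShift`), giving the null distribution
#' against which an observed MI can be compared. No threshold is
#' applied; significance judgment is left to the user.
#'
#' @inheritParams pacWaveletPhasePower
#' @param ampBand modulated band `c(fLow, fHigh)` in Hz.
#' @param n number of surrogates.
#' @param minShift minimal shift in seconds (default 1).
#' @param seed RNG seed for the shift draws.
#' @return numeric vector of `n` surrogate MI values.
#' @export
pacSurrogates <- function(sigPhase, sigAmp = sigPhase, phaseBand, ampBand,
                          nBins = 18L, n = 100L, minShift = 1,
                          seed = NULL, filterOrder = 2L) {
  if (!is.null(seed)) set.seed(seed)
  dur <- length(sigAmp@samples) / sigAmp@fs
  if (dur <= 2 * minShift)
    stop("signal too short for shifts of at least ", minShift, " s")
  dp <- filterAndDecompose(sigPhase,
          bandFilterSpec(phaseBand[1L], phaseBand[2L], filterOrder,
                         sigPhase@fs))
  da <- filterAndDecompose(sigAmp,
          bandFilterSpec(ampBand[1L], ampBand[2L], filterOrder,
                         sigAmp@fs))
  env <- channelSignal(da@envelope, sigAmp@fs)
  shifts <- stats::runif(n, minShift, dur - minShift)
  vapply(shifts, function(s) {
    shifted <- circularShift(env, s)@samples
    klFromNormalized(
      phaseAmplitudeProfile(dp@phase, shifted, nBins)@normalized)
  }, numeric(1L))
}
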