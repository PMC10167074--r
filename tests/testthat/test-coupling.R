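test_that("phase-amplitude profiles bin correctly", {
  phi <- seq(-pi + 1e-4, pi, length.out = 7200)
  unif <- phaseAmplitudeProfile(phi, rep(2.5, 7200), 18)
  expect_equal(unif@normalized, rep(1 / 18, 18), tolerance = 1e-9)
  ## cosine-modulated amplitude reproduces the closed-form profile
  prof <- phaseAmplitudeProfile(phi, 1 + cos(phi), 18)
  centers <- binCenters(prof)
  expected <- (1 + cos(centers)) / sum(1 + cos(centers))
  expect_equal(prof@normalized, expected, tolerance = 0.02)
  ## jointly permuting the pairs changes nothing
  set.seed(15)
  ord <- sample(7200)
  perm <- phaseAmplitudeProfile(phi[ord], (1 + cos(phi))[ord], 18)
  expect_equal(perm@normalized, prof@normalized)
  ## an uncovered bin is an error
  expect_error(phaseAmplitudeProfile(runif(100, 0, 1), rep(1, 100), 18),
               "empty phase bin")
})

test_that("KL modulation index hits its analytic extremes", {
  phi <- seq(-pi + 1e-4, pi, length.out = 3600)
  unif <- phaseAmplitudeProfile(phi, rep(1, 3600), 18)
  expect_identical(modulationIndex(unif), 0)
  ## all amplitude inside one bin
  onebin <- phaseAmplitudeProfile(phi, as.numeric(phi > -pi & phi <= -pi + 2 * pi / 18), 18)
  expect_equal(modulationIndex(onebin), 1)
  ## random profiles stay inside [0, 1]
  set.seed(16)
  for (i in 1:20) {
    p <- phaseAmplitudeProfile(runif(4000, -pi, pi), rexp(4000), 18)
    mi <- modulationIndex(p)
    expect_gte(mi, 0); expect_lte(mi, 1)
  }
})

test_that("all three indices are scale-free and see coupling", {
  sig <- makePacSignal(duration = 20, seed = 20)
  dp <- filterAndDecompose(sig, bandFilterSpec(7, 9, 2, 1000))
  da <- filterAndDecompose(sig, bandFilterSpec(64, 96, 6, 1000))
  flat <- makePacSignal(duration = 20, depth = 0, seed = 20)
  dp0 <- filterAndDecompose(flat, bandFilterSpec(7, 9, 2, 1000))
  da0 <- filterAndDecompose(flat, bandFilterSpec(64, 96, 6, 1000))
  for (m in c("kl_mi", "mvl", "plv")) {
    coupled <- modulationIndex(dp@phase, da@envelope, method = m,
                               fs = 1000, phaseBand = c(7, 9))
    uncoupled <- modulationIndex(dp0@phase, da0@envelope, method = m,
                                 fs = 1000, phaseBand = c(7, 9))
    scaled <- modulationIndex(dp@phase, 13 * da@envelope, method = m,
                              fs = 1000, phaseBand = c(7, 9))
    expect_gt(coupled, uncoupled)
    expect_equal(scaled, coupled, tolerance = 1e-9)
  }
  expect_error(modulationIndex(dp@phase, da@envelope, method = "plv"),
               "fs and phaseBand")
  prof <- phaseAmplitudeProfile(dp@phase, da@envelope)
  expect_error(modulationIndex(prof, method = "mvl"), "raw")
})

test_that("a small comodulogram recovers the planted coupling pair", {
  sig <- makePacSignal(duration = 20, seed = 21)
  cm <- comodulogram(sig, phaseRange = c(4, 12), ampRange = c(50, 110),
                     pStep = 2, aStep = 10)
  pk <- arrayInd(which.max(miValue(cm)), dim(miValue(cm)))
  expect_lte(abs(cm@phaseFreqs[pk[2]] - 8), 2)
  expect_lte(abs(cm@ampFreqs[pk[1]] - 80), 10)
  ## single-channel mode is symmetric in its two signal arguments
  cm2 <- comodulogram(sig, sig, phaseRange = c(4, 12),
                      ampRange = c(50, 110), pStep = 2, aStep = 10)
  expect_equal(miValue(cm2), miValue(cm))
  expect_warning(comodulogram(sig, phaseRange = c(4, 8),
                              ampRange = c(5, 6), pStep = 2, aStep = 1),
                 "inverted")
})

test_that("wavelet phase-power profile peaks at the coupling phase", {
  sig <- makePacSignal(duration = 20, couplingPhase = 1.2, seed = 22)
  prof <- pacWaveletPhasePower(sig, phaseBand = c(7, 9),
                               ampRange = c(70, 90))
  expect_identical(prof@method, "wavelet_power")
  peak <- binCenters(prof)[which.max(prof@meanAmplitude)]
  expect_lt(abs(Arg(exp(1i * (peak - 1.2)))), 2 * pi / 18 + 1e-9)
  expect_gt(miValue(prof), 0)
  ## an unmodulated carrier gives a flat profile
  flat <- makePacSignal(duration = 20, depth = 0, seed = 22)
  pf <- pacWaveletPhasePower(flat, phaseBand = c(7, 9),
                             ampRange = c(70, 90))
  expect_lt(max(pf@meanAmplitude) / min(pf@meanAmplitude), 1.1)
})

test_that("per-trial profile averaging reduces to the single-trial case", {
  sig <- makePacSignal(duration = 4, seed = 23)
  ts <- makeTrialSet(rbind(samples(sig), samples(sig)))
  avg <- pacWaveletPhasePower(perTrial = ts, phaseBand = c(7, 9),
                              ampRange = c(70, 90))
  single <- pacWaveletPhasePower(channelSignal(samples(sig), 1000),
                                 phaseBand = c(7, 9),
                                 ampRange = c(70, 90))
  expect_equal(avg@meanAmplitude, single@meanAmplitude, tolerance = 1e-9)
})

test_that("cycle detection counts the cycles of a clean sine", {
  sig <- unitSine(8, duration = 10)
  d <- filterAndDecompose(sig, bandFilterSpec(7, 9, 2, 1000))
  cyc <- detectCycles(d, c(7, 9))
  expect_gte(nrow(cyc@windows), 78)
  expect_lte(nrow(cyc@windows), 80)
  dur <- (cyc@windows[, 2] - cyc@windows[, 1]) / 1000
  expect_lt(max(abs(dur - 0.125)), 0.01)
  ## windows are ordered and non-overlapping
  expect_true(all(diff(cyc@windows[, 1]) > 0))
  expect_true(all(cyc@windows[-1, 1] > cyc@windows[-nrow(cyc@windows), 2]))
  expect_error(detectCycles(d, c(3, 5)), "band")
})

test_that("cycles are not accepted where the rhythm is silent", {
  sil <- makePacSignal(duration = 30, bursts = rbind(c(0, 10), c(20, 30)),
                       snr = 10, seed = 24)
  d <- filterAndDecompose(sil, bandFilterSpec(7, 9, 2, 1000))
  cyc <- detectCycles(d, c(7, 9))
  inSilent <- cyc@windows[, 1] > 10500 & cyc@windows[, 2] < 19500
  expect_identical(sum(inSilent), 0L)
  expect_gt(nrow(cyc@windows), 100)             # bursts are covered
})

test_that("cycle-based PAC agrees with the wavelet method when stationary", {
  sig <- makePacSignal(duration = 20, seed = 25)
  pw <- pacWaveletPhasePower(sig, phaseBand = c(7, 9),
                             ampRange = c(70, 90))
  pc <- pacCycleBased(sig, phaseBand = c(7, 9), ampRange = c(70, 90))
  expect_identical(pc@method, "cycle_power")
  cosSim <- sum(pw@normalized * pc@normalized) /
    sqrt(sum(pw@normalized^2) * sum(pc@normalized^2))
  expect_gt(cosSim, 0.95)
  ## degenerate two-channel mode equals single-channel mode
  pc2 <- pacCycleBased(sig, sig, phaseBand = c(7, 9),
                       ampRange = c(70, 90))
  expect_equal(pc2@meanAmplitude, pc@meanAmplitude)
})

test_that("the cycle method resists dilution by coupling-free stretches", {
  si <- makePacSignal(duration = 30, bursts = intermittentBursts(30),
                      seed = 26)
  pw <- pacWaveletPhasePower(si, phaseBand = c(7, 9),
                             ampRange = c(70, 90))
  pc <- pacCycleBased(si, phaseBand = c(7, 9), ampRange = c(70, 90))
  expect_gt(miValue(pc), 2 * miValue(pw))
})

test_that("phase coherence is exact for a channel with itself", {
  set.seed(27)
  sig <- channelSignal(rnorm(8000), 1000)
  pcm <- phaseCoherence(sig, sig, wdTime = 1, fLow = 6, fHigh = 14)
  expect_lt(max(abs(pcm@pc - 1)), 1e-9)
  expect_error(phaseCoherence(sig, channelSignal(rnorm(100), 1000),
                              wdTime = 1, fLow = 6, fHigh = 14),
               "length")
})

test_that("a constant lag does not break narrowband coherence", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  a <- channelSignal(sin(2 * pi * 10 * t), 1000)
  b <- circularShift(a, 0.02)                   # 72 degrees at 10 Hz
  pcm <- phaseCoherence(a, b, wdTime = 1, fLow = 8, fHigh = 12,
                        nFreqWindows = 2)
  expect_gt(min(pcm@pc), 0.97)
})

test_that("independent noise gives low coherence that falls with window", {
  set.seed(28)
  n1 <- channelSignal(rnorm(20000), 1000)
  n2 <- channelSignal(rnorm(20000), 1000)
  pc1 <- phaseCoherence(n1, n2, wdTime = 1, fLow = 6, fHigh = 14)
  pc2 <- phaseCoherence(n1, n2, wdTime = 2, fLow = 6, fHigh = 14)
  expect_lt(mean(pc1@pc), 0.3)
  expect_lt(mean(pc2@pc), mean(pc1@pc))
  expect_true(all(pc1@pc >= 0 & pc1@pc <= 1))
})

test_that("surrogate shifts collapse the index of a drifting-phase fixture", {
  sj <- makePacSignal(duration = 30, phaseJitter = 5, seed = 29)
  dp <- filterAndDecompose(sj, bandFilterSpec(7, 9, 2, 1000))
  da <- filterAndDecompose(sj, bandFilterSpec(64, 96, 6, 1000))
  mi0 <- modulationIndex(dp@phase, da@envelope, method = "kl_mi")
  sur <- pacSurrogates(sj, phaseBand = c(7, 9), ampBand = c(64, 96),
                       n = 20, minShift = 1, seed = 1)
  expect_length(sur, 20)
  expect_lt(max(sur), 0.1 * mi0)
})
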