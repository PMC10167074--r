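test_that("band-pass response has Butterworth landmarks", {
  ## away from DC the bilinear band transform preserves the analog
  ## -3 dB edges essentially exactly
  des <- designBandpass(bandFilterSpec(30, 50, 4, 1000),
                        at = c(30, 50, sqrt(1500)))
  g <- function(d, f)
    d$response$gain_db[which.min(abs(d$response$freq_hz - f))]
  ## table reports the forward-backward (squared) response:
  ## -3 dB per pass at each edge -> -6.02 dB effective
  expect_equal(g(des, 30), -6.0206, tolerance = 1e-3)
  expect_equal(g(des, 50), -6.0206, tolerance = 1e-3)
  expect_lt(abs(g(des, sqrt(1500))), 0.01)      # geometric mid-band
  ## low-frequency band: edges warp slightly toward DC, but mid-band
  ## and stop-band contracts hold
  low <- designBandpass(bandFilterSpec(4, 8, 4, 1000),
                        at = c(4, 8, sqrt(32), 40))
  expect_equal(g(low, 4), -6.0206, tolerance = 0.2)   # relative
  expect_equal(g(low, 8), -6.0206, tolerance = 0.2)
  expect_lt(abs(g(low, sqrt(32))), 0.1)
  expect_lt(g(low, 40), -40)                    # stop-band
})

test_that("unstable narrow designs are rejected with guidance", {
  expect_error(designBandpass(bandFilterSpec(4, 4.2, 8, 20000)),
               "unstable|order")
  expect_error(bandFilterSpec(8, 4, 4, 1000), "fLow < fHigh")
})

test_that("analytic decomposition recovers envelope and phase of a sine", {
  sig <- unitSine(10)
  d <- filterAndDecompose(sig, bandFilterSpec(8, 12, 4, 1000))
  mid <- 2000:8000
  expect_lt(max(abs(d@envelope[mid] - 1)), 0.02)
  ## phase advances 2*pi per period: unwrapped slope = 2*pi*10
  dphi <- diff(d@phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi) * 1000, 2 * pi * 10, tolerance = 0.01)
  ## out-of-band tone is rejected
  d2 <- filterAndDecompose(unitSine(40), bandFilterSpec(8, 12, 4, 1000))
  expect_lt(max(d2@envelope[mid]), 0.01)
  expect_error(filterAndDecompose(channelSignal(rnorm(10), 1000),
                                  bandFilterSpec(8, 12, 4, 1000)),
               "too short")
})

test_that("amplitude modulation is recovered from the envelope", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  x <- (1 + 0.5 * cos(2 * pi * 2 * t)) * cos(2 * pi * 40 * t)
  d <- filterAndDecompose(channelSignal(x, 1000),
                          bandFilterSpec(30, 50, 4, 1000))
  mid <- 1000:9000
  expect_gt(cor(d@envelope[mid], 1 + 0.5 * cos(2 * pi * 2 * t)[mid]),
            0.99)
})

test_that("zero-phase filtering introduces no group delay", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  x <- sin(2 * pi * 10 * t)
  d <- filterAndDecompose(channelSignal(x, 1000),
                          bandFilterSpec(8, 12, 4, 1000))
  cc <- stats::ccf(d@filtered, x, lag.max = 25, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf), 1, 1], 0)
})

test_that("FFT spectrum localizes tones with correct magnitude ratios", {
  sp <- fftSpectrum(unitSine(10))
  expect_equal(sp@freqs[which.max(sp@power)], 10)
  expect_equal(max(sp@power), 1, tolerance = 1e-6)
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  two <- channelSignal(sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 40 * t),
                       1000)
  sp2 <- fftSpectrum(two)
  m10 <- max(sp2@power[abs(sp2@freqs - 10) < 0.5])
  m40 <- max(sp2@power[abs(sp2@freqs - 40) < 0.5])
  expect_equal(m10 / m40, 2, tolerance = 0.01)
  ## average of identical trials equals the single-trial spectrum
  ts <- makeTrialSet(rbind(samples(two), samples(two), samples(two)))
  expect_equal(fftSpectrum(ts, average = TRUE)@power, sp2@power)
})

test_that("spectrum magnitude is invariant to circular time shift", {
  set.seed(10)
  x <- rnorm(4000)
  a <- fftSpectrum(channelSignal(x, 1000))
  b <- fftSpectrum(circularShift(channelSignal(x, 1000), 0.731))
  expect_equal(a@power, b@power, tolerance = 1e-9)
})

test_that("Welch PSD satisfies Parseval and quadratic amplitude scaling", {
  set.seed(11)
  x <- rnorm(20000, sd = 1.7)
  sig <- channelSignal(x, 1000)
  ps <- welchPsd(sig, segLen = 1)
  expect_equal(pracma::trapz(ps@freqs, ps@power), var(x),
               tolerance = 0.1)
  ps2 <- welchPsd(channelSignal(2 * x, 1000), segLen = 1)
  expect_equal(ps2@power, 4 * ps@power, tolerance = 1e-9)
  tone <- welchPsd(unitSine(25), segLen = 2)
  expect_equal(tone@freqs[which.max(tone@power)], 25, tolerance = 0.5)
  expect_error(welchPsd(sig, segLen = 30), "exceeds")
})

test_that("band power integrates and normalizes correctly", {
  ps <- welchPsd(unitSine(10, duration = 20), segLen = 2)
  expect_equal(bandPower(ps, 0, 500, relative = TRUE), 1,
               tolerance = 1e-9)
  expect_gt(bandPower(ps, 8, 12, relative = TRUE), 0.95)
  ## disjoint partition adds to one
  cuts <- seq(0, 500, length.out = 6)
  parts <- vapply(seq_len(5), function(i)
    bandPower(ps, cuts[i], cuts[i + 1], relative = TRUE), 0)
  expect_equal(sum(parts), 1, tolerance = 1e-6)
  expect_error(bandPower(ps, 400, 600), "outside")
})
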