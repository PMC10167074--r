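test_that("a pure tone concentrates scalogram power at its frequency", {
  sc <- morletTransform(unitSine(40), 20, 60, nFreqs = 41)
  expect_equal(sc@freqs[which.max(rowMeans(sc@power))], 40)
  expect_equal(max(sc@power), 1, tolerance = 0.05)
  ## quadratic amplitude scaling
  sc2 <- morletTransform(unitSine(40, amp = 2), 20, 60, nFreqs = 41)
  expect_equal(sc2@power, 4 * sc@power, tolerance = 1e-6)
})

test_that("sequential tones are localized in their own half-intervals", {
  t <- seq(0, 5 - 1e-3, by = 1e-3)
  x <- c(sin(2 * pi * 10 * t), sin(2 * pi * 40 * t))
  sc <- morletTransform(channelSignal(x, 1000), 5, 50, nFreqs = 46)
  i10 <- which.min(abs(sc@freqs - 10))
  i40 <- which.min(abs(sc@freqs - 40))
  first <- 500:4500; second <- 5500:9500
  expect_gt(mean(sc@power[i10, first]), 10 * mean(sc@power[i10, second]))
  expect_gt(mean(sc@power[i40, second]), 10 * mean(sc@power[i40, first]))
})

test_that("trial-averaged scalograms average power, not coefficients", {
  set.seed(12)
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  burst <- exp(-((t - 0.15) / 0.03)^2) * sin(2 * pi * 80 * t)
  trials <- t(replicate(8, burst + rnorm(length(t), sd = 0.3)))
  ts <- makeTrialSet(trials)
  sc <- scalogramAverage(ts, 40, 120, nFreqs = 41)
  pk <- arrayInd(which.max(sc@power), dim(sc@power))
  expect_lt(abs(sc@freqs[pk[1]] - 80), 8)
  expect_gt(sc@times[pk[2]], 0.1); expect_lt(sc@times[pk[2]], 0.2)
  ## identical trials reduce to the single-trial transform
  same <- makeTrialSet(rbind(burst, burst))
  scs <- scalogramAverage(same, 40, 120, nFreqs = 21)
  sc1 <- morletTransform(channelSignal(burst, 1000), 40, 120, nFreqs = 21)
  expect_equal(scs@power, sc1@power, tolerance = 1e-9)
})

test_that("display transforms normalize rows and reference the maximum", {
  set.seed(13)
  sc <- morletTransform(channelSignal(rnorm(4000), 1000), 5, 50,
                        nFreqs = 10)
  nm <- transformScalogram(sc, normalize = TRUE)
  expect_lt(max(abs(rowMeans(nm@power))), 1e-9)
  expect_identical(nm@transformState, "normalized")
  lg <- transformScalogram(sc, log = TRUE)
  expect_equal(max(lg@power), 0)
  both <- transformScalogram(sc, normalize = TRUE, log = TRUE)
  expect_identical(both@transformState, "normalized+log")
  expect_error(transformScalogram(lg, log = TRUE), "already")
  expect_error(transformScalogram(nm, normalize = TRUE), "already")
})

test_that("normalization flattens the 1/f tilt of broadband noise", {
  set.seed(14)
  ## AR(1) noise has a sloped spectrum; raw row means differ widely
  x <- as.numeric(stats::filter(rnorm(8000), 0.95, method = "recursive"))
  sc <- morletTransform(channelSignal(x, 1000), 5, 100, nFreqs = 20)
  rawSpread <- diff(range(rowMeans(sc@power)))
  nm <- transformScalogram(sc, normalize = TRUE)
  expect_lt(max(abs(rowMeans(nm@power))), 1e-9)
  expect_gt(rawSpread, 1e-3)                    # there was a tilt to remove
})

test_that("more cycles narrow the frequency marginal of a tone", {
  sig <- unitSine(40, duration = 8)
  spread <- vapply(c(3, 5, 7, 9, 12), function(nc) {
    sc <- morletTransform(sig, 20, 60, nFreqs = 81, nCycles = nc)
    marg <- rowMeans(sc@power)
    w <- marg / sum(marg)
    mu <- sum(w * sc@freqs)
    sqrt(sum(w * (sc@freqs - mu)^2))
  }, 0)
  expect_true(all(diff(spread) < 0))
})

test_that("band limits are validated", {
  expect_error(morletTransform(unitSine(10, 2), 10, 600), "Nyquist")
  expect_error(morletTransform(unitSine(10, 2), 10, 40, nCycles = 2),
               "nCycles")
})
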