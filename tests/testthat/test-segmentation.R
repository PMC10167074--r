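test_that("stimulus detection recovers every pulse of a clean train", {
  rec <- makeStimRecording(fs = 1000, nTrials = 10, isi = 3,
                           noiseSd = 0, seed = 1)
  train <- detectStimuli(getChannel(rec, "stim"), threshold = 2.5,
                         isiNominal = 3)
  expect_length(eventTimes(train), 10)
  expect_lt(max(abs(eventTimes(train) - rec@meta$stimTimes)), 1.5 / 1000)
})

test_that("detection count is threshold-invariant on square pulses", {
  rec <- makeStimRecording(fs = 1000, nTrials = 8, isi = 2,
                           noiseSd = 0, seed = 2)
  stim <- getChannel(rec, "stim")
  ref <- eventTimes(detectStimuli(stim, 2.5, 2))
  for (thr in c(0.5, 1.5, 3.5, 4.5)) {
    tt <- eventTimes(detectStimuli(stim, thr, 2))
    expect_length(tt, 8)
    expect_lt(max(abs(tt - ref)), 2 / 1000)
  }
})

test_that("a flat stimulation channel raises an empty-train error", {
  flat <- channelSignal(numeric(5000), 1000)
  expect_error(detectStimuli(flat, 1, 3), "no threshold crossings")
})

test_that("nonpositive thresholds warn but proceed", {
  rec <- makeStimRecording(fs = 1000, nTrials = 3, isi = 1,
                           noiseSd = 0, seed = 3)
  shifted <- channelSignal(samples(getChannel(rec, "stim")) - 1, 1000)
  expect_warning(train <- detectStimuli(shifted, -0.5, 1),
                 "threshold")
  expect_length(eventTimes(train), 3)
})

test_that("paired-pulse protocols need the declared intra-pair interval", {
  rec <- makeStimRecording(fs = 1000, nTrials = 10, isi = 3,
                           pairedInterval = 0.1, noiseSd = 0, seed = 4)
  stim <- getChannel(rec, "stim")
  ## without the declaration the second pulse falls in the refractory gap
  expect_length(eventTimes(detectStimuli(stim, 2.5, 3)), 10)
  withPair <- detectStimuli(stim, 2.5, 3, pairedInterval = 0.1)
  expect_length(eventTimes(withPair), 20)
})

test_that("trial windows have the documented arithmetic", {
  rec <- makeStimRecording(fs = 1000, nTrials = 10, isi = 3,
                           noiseSd = 0, seed = 5)
  train <- detectStimuli(getChannel(rec, "stim"), 2.5, 3)
  ts <- segmentTrials(getChannel(rec, 1), train, -0.5, 1.0)
  expect_identical(dim(trialData(ts)), c(10L, 1501L))
  expect_equal(timeAxis(ts)[1], -0.5)
  expect_equal(timeAxis(ts)[1501], 1.0, tolerance = 1e-9)
})

test_that("trial selection filters by original 1-based trial number", {
  rec <- makeStimRecording(fs = 1000, nTrials = 10, isi = 1,
                           noiseSd = 0, seed = 6)
  train <- detectStimuli(getChannel(rec, "stim"), 2.5, 1)
  ts <- segmentTrials(getChannel(rec, 1), train, -0.1, 0.4,
                      selection = c(2, 5, 9))
  expect_identical(trialIds(ts), c(2L, 5L, 9L))
  expect_identical(nrow(trialData(ts)), 3L)
  expect_error(segmentTrials(getChannel(rec, 1), train, -0.1, 0.4,
                             selection = c(2, 11, 15)),
               "11, 15")
})

test_that("the evoked response lands at the inserted latency in every trial", {
  rec <- makeStimRecording(fs = 1000, nTrials = 6, isi = 1,
                           noiseSd = 0, seed = 7)
  train <- detectStimuli(getChannel(rec, "stim"), 2.5, 1)
  ts <- segmentTrials(getChannel(rec, 1), train, -0.2, 0.5)
  ## template peaks tau = 10 ms after onset; onset latency 20 ms
  expected <- rec@meta$responseLatency + 0.01
  for (i in seq_len(nTrials(ts))) {
    pk <- timeAxis(ts)[which.max(trialData(ts)[i, ])]
    expect_lt(abs(pk - expected), 2.5 / 1000)
  }
})

test_that("edge-overrunning trials are dropped with a warning", {
  rec <- makeStimRecording(fs = 1000, nTrials = 5, isi = 1, preTime = 0.3,
                           noiseSd = 0, seed = 8)
  train <- detectStimuli(getChannel(rec, "stim"), 2.5, 1)
  expect_warning(ts <- segmentTrials(getChannel(rec, 1), train, -0.5, 0.4),
                 "dropped")
  expect_identical(trialIds(ts), 2:5)
})

test_that("window and no-stim contracts hold", {
  rec <- makeStimRecording(fs = 1000, nTrials = 3, isi = 1,
                           noiseSd = 0, seed = 9)
  sig <- getChannel(rec, 1)
  train <- detectStimuli(getChannel(rec, "stim"), 2.5, 1)
  expect_error(segmentTrials(sig, train, 0.5, 0.5), "tInitial")
  noStim <- segmentTrials(sig, NULL, 0, 0)
  expect_identical(nrow(trialData(noStim)), 1L)
  expect_equal(trialData(noStim)[1, ], samples(sig))
})
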