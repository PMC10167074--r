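# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so expected values frozen in the tests stay valid.

# Two-channel recording with sinusoids, for IO round trips.
makeIoRecording <- function(fs = 1000, duration = 10) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  new("Recording",
      data = rbind(sin(2 * pi * 7 * t) + 0.3 * sin(2 * pi * 31 * t),
                   0.5 * cos(2 * pi * 3 * t)),
      fs = fs, channelLabels = c("lfp", "aux"), units = c("mV", "mV"),
      sourcePath = "", meta = list())
}

# TrialSet built directly from a matrix (bypasses segmentation).
makeTrialSet <- function(mat, fs = 1000, t0 = 0) {
  new("TrialSet", data = mat, fs = fs,
      tAxis = t0 + (seq_len(ncol(mat)) - 1L) / fs,
      trialIds = seq_len(nrow(mat)))
}

unitSine <- function(freq, duration = 10, fs = 1000, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  channelSignal(amp * sin(2 * pi * freq * t), fs)
}

# Burst schedule used by the intermittent-coupling fixtures: 2 s of slow
# rhythm every 5 s.
intermittentBursts <- function(duration = 60)
  cbind(seq(0, duration - 5, by = 5), seq(2, duration - 3, by = 5))
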