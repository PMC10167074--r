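#' Load an ABF or EDF recording
#'
#' Reads a digitized multichannel recording into a [Recording-class].
#' With `format = "auto"` the format is resolved from the file content
#' (magic bytes), not the extension: ABF1 files start with `"ABF "`,
#' ABF2 with `"ABF2"`, EDF with an ASCII `"0"` version field. Episodic
#' ABF sweeps are concatenated in acquisition order into one continuous
#' per-channel trace (sweep boundaries are kept in `meta`); trial
#' structure is recovered downstream from the stimulus channel with
#' [detectStimuli()] and [segmentTrials()].
#'
#' @param path path to the file.
#' @param format `"auto"` (default), `"abf"` or `"edf"`.
#' @return a [Recording-class]; channels x samples, no NA values.
#' @examples
#' rec <- makeStimRecording(fs = 1000, nTrials = 3, isi = 1, seed = 1)
#' f <- tempfile(fileext = ".edf")
#' writeEdf(rec, f)
#' loadRecording(f)
#' @export
loadRecording <- function(path, format = c("auto", "abf", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 8L)
    head4 <- rawToChar(magic[seq_len(min(4L, length(magic)))])
    format <- if (head4 %in% c("ABF ", "ABF2")) "abf"
    else if (length(magic) >= 8L &&
             trimws(rawToChar(magic)) == "0") "edf"
    else stop("unsupported or unrecognized format: ", path,
              " (expected ABF or EDF magic bytes)")
  }
  rec <- switch(format, abf = readAbf(path), edf = readEdf(path))
  if (anyNA(rec@data))
    stop("recording contains NA samples after loading: ", path)
  rec
}

#' Resample a recording to a lower rate
#'
#' Applies a zero-phase anti-aliasing low-pass (8th-order Butterworth,
#' cutoff 0.4 x `targetFs`, forward-backward) to every channel, then
#' polyphase-resamples to `targetFs`. Non-integer decimation ratios are
#' supported through rational resampling. Upsampling is out of contract.
#'
#' @param rec a [Recording-class].
#' @param targetFs desired sampling frequency in Hz; must satisfy
#'   `0 < targetFs <= samplingRate(rec)`.
#' @return a [Recording-class] at `targetFs` with the same channels;
#'   duration preserved within one sample period.
#' @export
resampleRecording <- function(rec, targetFs) {
  stopifnot(is(rec, "Recording"))
  if (!is.numeric(targetFs) || targetFs <= 0)
    stop("targetFs must be positive")
  if (targetFs > rec@fs)
    stop("targetFs (", targetFs, " Hz) exceeds the recording rate (",
         rec@fs, " Hz); upsampling is not supported")
  if (isTRUE(all.equal(targetFs, rec@fs))) return(rec)

  ratio <- rationalApprox(targetFs / rec@fs)
  p <- ratio[1L]; q <- ratio[2L]
  aa <- signal::butter(8, 0.4 * targetFs / (rec@fs / 2), type = "low")
  nOut <- floor(ncol(rec@data) * p / q)
  out <- matrix(0, nrow = nrow(rec@data), ncol = nOut)
  for (i in seq_len(nrow(rec@data))) {
    low <- signal::filtfilt(aa, rec@data[i, ])
    res <- signal::resample(low, p, q)
    out[i, ] <- res[seq_len(nOut)]
  }
  new("Recording", data = out, fs = rec@fs * p / q,
      channelLabels = rec@channelLabels, units = rec@units,
      sourcePath = rec@sourcePath,
      meta = c(rec@meta, list(resampledFrom = rec@fs)))
}

## Smallest rational p/q approximating x within 1e-9 (q capped).
rationalApprox <- function(x, maxDenom = 10000L) {
  for (q in seq_len(maxDenom)) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < 1e-9) return(c(p, q))
  }
  stop("cannot express the resampling ratio ", x,
       " as a manageable rational; choose a rounder target rate")
}

#' Extract one channel of a recording
#'
#' @param rec a [Recording-class].
#' @param channel 1-based channel index or a channel label.
#' @return a [ChannelSignal-class] (`t0 = 0`).
#' @export
getChannel <- function(rec, channel) {
  stopifnot(is(rec, "Recording"))
  if (is.character(channel)) {
    idx <- match(channel, rec@channelLabels)
    if (is.na(idx)) stop("no channel labelled '", channel, "'")
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > nrow(rec@data))
      stop("channel index ", idx, " out of range 1..", nrow(rec@data))
  }
  channelSignal(rec@data[idx, ], rec@fs, meta = rec@meta)
}
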