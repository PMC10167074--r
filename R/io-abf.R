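## Axon Binary Format, version 1.x.
##
## The ABF1 container is a fixed 2048-byte binary header followed by
## multiplexed sample data. The reader supports the subset used for LFP /
## patch recordings exported by acquisition software: int16 (with the
## standard instrument scaling chain) or float32 samples, gap-free or
## episodic acquisition. Episodic sweeps are concatenated in acquisition
## order into one continuous per-channel trace; the sweep count and
## per-sweep length are retained in `meta` so downstream segmentation can
## stay stimulus-driven. ABF2 ("ABF2" signature) files are recognized and
## rejected with an explicit message. The writer emits gap-free float32
## files (no scaling chain), which round-trip exactly.

abfReadAt <- function(raw, offset, what, n = 1L, size = NA_integer_) {
  con <- rawConnection(raw)
  on.exit(close(con))
  seek(con, offset)
  if (what == "character") {
    b <- readBin(con, "raw", n = n)
    return(trimws(rawToChar(b[b != as.raw(0L)])))
  }
  readBin(con, what, n = n, size = size, endian = "little")
}

readAbf <- function(path) {
  fsize <- file.info(path)$size
  raw <- readBin(path, "raw", n = fsize)
  if (length(raw) < 2048L) stop("ABF file truncated: header incomplete")
  sig <- rawToChar(raw[1:4])
  if (sig == "ABF2")
    stop("ABF2 files are not supported by this reader; ",
         "export as ABF1 or EDF")
  if (sig != "ABF ")
    stop("not an ABF file: signature is '", sig, "'")

  opMode <- abfReadAt(raw, 8L, "integer", size = 2L)
  acqLength <- abfReadAt(raw, 10L, "integer", size = 4L)
  nEpisodes <- abfReadAt(raw, 16L, "integer", size = 4L)
  dataPtr <- abfReadAt(raw, 40L, "integer", size = 4L)
  dataFormat <- abfReadAt(raw, 100L, "integer", size = 2L)
  nch <- abfReadAt(raw, 120L, "integer", size = 2L)
  adcInterval <- abfReadAt(raw, 122L, "numeric", size = 4L)
  samplesPerEpisode <- abfReadAt(raw, 138L, "integer", size = 4L)
  adcRange <- abfReadAt(raw, 244L, "numeric", size = 4L)
  adcResolution <- abfReadAt(raw, 252L, "integer", size = 4L)
  sampSeq <- abfReadAt(raw, 410L, "integer", n = 16L, size = 2L)
  instScale <- abfReadAt(raw, 922L, "numeric", n = 16L, size = 4L)
  instOffset <- abfReadAt(raw, 986L, "numeric", n = 16L, size = 4L)

  if (nch < 1L || nch > 16L)
    stop("ABF header: implausible channel count ", nch)
  if (acqLength < nch)
    stop("ABF header: lActualAcqLength (", acqLength, ") < channel count")
  labels <- vapply(seq_len(nch) - 1L, function(i)
    abfReadAt(raw, 442L + 10L * i, "character", n = 10L), "")
  unitStr <- vapply(seq_len(nch) - 1L, function(i)
    abfReadAt(raw, 602L + 8L * i, "character", n = 8L), "")
  labels[!nzchar(labels)] <- paste0("AD", seq_len(nch)[!nzchar(labels)] - 1L)
  unitStr[!nzchar(unitStr)] <- "mV"

  start <- dataPtr * 512L
  sampSize <- if (dataFormat == 1L) 4L else 2L
  if (start + acqLength * sampSize > length(raw))
    stop("ABF data section truncated: expected ", acqLength,
         " samples at byte ", start)
  con <- rawConnection(raw)
  on.exit(close(con))
  seek(con, start)
  vals <- if (dataFormat == 1L) {
    readBin(con, "numeric", n = acqLength, size = 4L, endian = "little")
  } else if (dataFormat == 0L) {
    readBin(con, "integer", n = acqLength, size = 2L, signed = TRUE,
            endian = "little")
  } else stop("ABF nDataFormat ", dataFormat, " is not supported")

  nPer <- acqLength %/% nch
  vals <- vals[seq_len(nPer * nch)]
  data <- matrix(vals, nrow = nch)          # de-multiplex
  if (dataFormat == 0L) {
    ch <- sampSeq[seq_len(nch)] + 1L        # physical ADC channel per row
    for (i in seq_len(nch)) {
      sc <- instScale[ch[i]]
      if (!is.finite(sc) || sc == 0) sc <- 1
      data[i, ] <- data[i, ] * adcRange / (adcResolution * sc) +
        instOffset[ch[i]]
    }
  }
  fs <- 1e6 / (adcInterval * nch)
  sweepLen <- if (opMode == 5L && nEpisodes > 0L)
    samplesPerEpisode %/% nch else nPer
  new("Recording", data = data, fs = fs, channelLabels = labels,
      units = unitStr, sourcePath = path,
      meta = list(format = "abf", operationMode = opMode,
                  nSweeps = max(nEpisodes, 1L), sweepLength = sweepLen))
}

#' Write a recording as an ABF1 file
#'
#' Writes a [Recording-class] as a gap-free ABF version 1 file with
#' float32 samples (lossless round trip, no instrument scaling chain).
#' Intended for fixture generation and data exchange with readers that
#' accept float ABF1.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadRecording()], [writeEdf()]
#' @export
writeAbf <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  nch <- nrow(rec@data)
  if (nch > 16L) stop("ABF1 supports at most 16 channels")
  n <- ncol(rec@data)
  hdr <- raw(2048L)
  poke <- function(hdr, offset, value, what, size) {
    b <- if (is.raw(value)) value
         else writeBin(value, raw(), size = size, endian = "little")
    hdr[(offset + 1L):(offset + length(b))] <- b
    hdr
  }
  hdr <- poke(hdr, 0L, charToRaw("ABF "), "raw", NA)
  hdr <- poke(hdr, 4L, 1.3, "numeric", 4L)
  hdr <- poke(hdr, 8L, 3L, "integer", 2L)              # gap-free
  hdr <- poke(hdr, 10L, as.integer(n * nch), "integer", 4L)
  hdr <- poke(hdr, 16L, 1L, "integer", 4L)
  hdr <- poke(hdr, 40L, 4L, "integer", 4L)             # data at byte 2048
  hdr <- poke(hdr, 100L, 1L, "integer", 2L)            # float32
  hdr <- poke(hdr, 120L, as.integer(nch), "integer", 2L)
  hdr <- poke(hdr, 122L, 1e6 / (rec@fs * nch), "numeric", 4L)
  hdr <- poke(hdr, 138L, as.integer(n * nch), "integer", 4L)
  hdr <- poke(hdr, 244L, 10, "numeric", 4L)
  hdr <- poke(hdr, 252L, 32768L, "integer", 4L)
  for (i in seq_len(16L))
    hdr <- poke(hdr, 410L + 2L * (i - 1L), i - 1L, "integer", 2L)
  for (i in seq_len(nch)) {
    lab <- substr(rec@channelLabels[i], 1L, 10L)
    hdr <- poke(hdr, 442L + 10L * (i - 1L),
                charToRaw(formatC(lab, width = -10L)), "raw", NA)
    un <- substr(rec@units[i], 1L, 8L)
    hdr <- poke(hdr, 602L + 8L * (i - 1L),
                charToRaw(formatC(un, width = -8L)), "raw", NA)
  }
  for (i in seq_len(16L)) {
    hdr <- poke(hdr, 922L + 4L * (i - 1L), 1, "numeric", 4L)
    hdr <- poke(hdr, 986L + 4L * (i - 1L), 0, "numeric", 4L)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(rec@data), con, size = 4L, endian = "little")
  invisible(path)
}
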