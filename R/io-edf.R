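## European Data Format (EDF/EDF+) continuous recordings.
##
## EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, then
## data records of 16-bit little-endian integers scaled linearly between
## per-signal digital and physical ranges. Only continuous recordings are
## supported (EDF+D discontinuous files are rejected); annotation signals
## are dropped on read.

edfField <- function(raw, from, len) {
  trimws(rawToChar(raw[(from + 1L):(from + len)]))
}

readEdfHeader <- function(con) {
  hdr <- readBin(con, "raw", n = 256L)
  if (length(hdr) < 256L) stop("EDF header truncated (< 256 bytes)")
  version <- edfField(hdr, 0L, 8L)
  if (version != "0")
    stop("not an EDF file: version field is '", version, "'")
  reserved <- edfField(hdr, 192L, 44L)
  if (startsWith(reserved, "EDF+D"))
    stop("EDF+D discontinuous recordings are not supported")
  nRecords <- as.integer(edfField(hdr, 236L, 8L))
  recDur <- as.numeric(edfField(hdr, 244L, 8L))
  ns <- as.integer(edfField(hdr, 252L, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF header: bad signal count")
  sig <- readBin(con, "raw", n = 256L * ns)
  if (length(sig) < 256L * ns) stop("EDF signal headers truncated")
  fld <- function(off, len) {
    vapply(seq_len(ns) - 1L,
           function(i) edfField(sig, off * ns + i * len, len), "")
  }
  list(
    nRecords = nRecords, recDur = recDur, ns = ns,
    labels = fld(0L, 16L),
    units = fld(96L, 8L),
    physMin = as.numeric(fld(104L, 8L)),
    physMax = as.numeric(fld(112L, 8L)),
    digMin = as.numeric(fld(120L, 8L)),
    digMax = as.numeric(fld(128L, 8L)),
    sprec = as.integer(fld(216L, 8L))
  )
}

readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEdfHeader(con)
  if (any(is.na(h$sprec)) || any(h$sprec < 1L))
    stop("EDF header: bad samples-per-record field")
  recLenVals <- sum(h$sprec)
  vals <- readBin(con, "integer", n = recLenVals * max(h$nRecords, 0L),
                  size = 2L, signed = TRUE, endian = "little")
  nRecords <- length(vals) %/% recLenVals
  if (h$nRecords >= 0L && nRecords < h$nRecords)
    stop("EDF data section truncated: expected ", h$nRecords,
         " records, found ", nRecords)
  if (nRecords < 1L) stop("EDF file contains no data records")
  vals <- vals[seq_len(nRecords * recLenVals)]
  keep <- !grepl("^EDF Annotations", h$labels)
  if (!any(keep)) stop("EDF file contains only annotation signals")
  fsAll <- h$sprec / h$recDur
  fs <- unique(fsAll[keep])
  if (length(fs) != 1L)
    stop("EDF channels have differing sampling rates (",
         paste(fs, collapse = ", "), " Hz); read them separately")
  offsets <- c(0L, cumsum(h$sprec))
  data <- matrix(0, nrow = sum(keep), ncol = nRecords * h$sprec[keep][1L])
  recMat <- matrix(vals, nrow = recLenVals, ncol = nRecords)
  row <- 0L
  for (i in seq_len(h$ns)) {
    if (!keep[i]) next
    row <- row + 1L
    dig <- as.numeric(recMat[(offsets[i] + 1L):offsets[i + 1L], ])
    gain <- (h$physMax[i] - h$physMin[i]) / (h$digMax[i] - h$digMin[i])
    data[row, ] <- (dig - h$digMin[i]) * gain + h$physMin[i]
  }
  new("Recording", data = data, fs = fs,
      channelLabels = h$labels[keep], units = h$units[keep],
      sourcePath = path,
      meta = list(format = "edf", nRecords = nRecords))
}

padField <- function(x, len) {
  x <- as.character(x)
  if (nchar(x) > len) x <- substr(x, 1L, len)
  formatC(x, width = -len)
}

numField <- function(x, len) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = len - 2L)
  if (nchar(s) > len) s <- substr(s, 1L, len)
  padField(s, len)
}

#' Write a recording as an EDF file
#'
#' Writes a [Recording-class] as a standard continuous EDF file (16-bit
#' samples, per-channel physical scaling over the observed amplitude
#' range). One data record per second is used when the sample count
#' divides evenly by `fs`; otherwise the whole trace is written as a
#' single record. Amplitudes are quantized to 1/65535 of the channel
#' range.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadRecording()], [writeAbf()]
#' @export
writeEdf <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  nch <- nrow(rec@data)
  n <- ncol(rec@data)
  fs <- rec@fs
  if (fs == round(fs) && n %% fs == 0) {
    sprec <- as.integer(fs)
    recDur <- 1
  } else {
    sprec <- n
    recDur <- n / fs
  }
  nRecords <- n %/% sprec
  physMin <- apply(rec@data, 1L, min)
  physMax <- apply(rec@data, 1L, max)
  flat <- physMax - physMin < .Machine$double.eps
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768
  digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8L),
    padField("X X X X", 80L),
    padField("Startdate X X X X", 80L),
    padField("01.01.00", 8L), padField("00.00.00", 8L),
    numField(256L * (nch + 1L), 8L),
    padField("", 44L),
    numField(nRecords, 8L),
    numField(recDur, 8L),
    numField(nch, 4L),
    paste(vapply(rec@channelLabels, padField, "", len = 16L), collapse = ""),
    paste(rep(padField("", 80L), nch), collapse = ""),
    paste(vapply(rec@units, padField, "", len = 8L), collapse = ""),
    paste(vapply(physMin, numField, "", len = 8L), collapse = ""),
    paste(vapply(physMax, numField, "", len = 8L), collapse = ""),
    paste(rep(numField(digMin, 8L), nch), collapse = ""),
    paste(rep(numField(digMax, 8L), nch), collapse = ""),
    paste(rep(padField("", 80L), nch), collapse = ""),
    paste(rep(numField(sprec, 8L), nch), collapse = ""),
    paste(rep(padField("", 32L), nch), collapse = "")
  )
  writeBin(charToRaw(hdr), con)
  dig <- matrix(0L, nrow = nch, ncol = n)
  for (i in seq_len(nch)) {
    gain <- (digMax - digMin) / (physMax[i] - physMin[i])
    dig[i, ] <- as.integer(round((rec@data[i, ] - physMin[i]) * gain) +
                             digMin)
  }
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * sprec + 1L):(r * sprec)
    for (i in seq_len(nch))
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}
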