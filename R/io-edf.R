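## Minimal single-record EDF (European Data Format) reader/writer.
##
## EDF stores an ASCII header (256 bytes + 256 per signal) followed by
## little-endian 16-bit samples, scaled linearly between per-signal digital
## and physical ranges. This implementation writes one data record spanning
## the whole recording and reads any record layout back; it covers the
## plain-EDF subset (no EDF+ annotations).

edfPad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  formatC(s, width = -width)          # left-justified, space padded
}

edfNum <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 5, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "e", digits = 1, width = -1)
  edfPad(s, width)
}

#' Write a recording in EDF format
#'
#' All channels share the sampling rate; samples are quantized to the
#' 16-bit digital range over a symmetric physical range just covering the
#' data.
#'
#' @param rec an \linkS4class{EEGRecording}
#' @param path output path
#' @return the path, invisibly
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  data <- rec@data
  ns <- nrow(data)
  nsamp <- ncol(data)
  physMax <- vapply(seq_len(ns), function(i) {
    m <- max(abs(data[i, ]), 1e-12)
    as.numeric(formatC(m * 1.001, format = "e", digits = 1))
  }, numeric(1))
  digMax <- 32767; digMin <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edfPad("0", 8))                          # version
  wr(edfPad("local patient", 80))
  wr(edfPad("local recording", 80))
  wr(edfPad("01.01.00", 8)); wr(edfPad("00.00.00", 8))
  wr(edfPad(256 * (ns + 1), 8))               # header bytes
  wr(edfPad("", 44))
  wr(edfPad(1, 8))                            # one data record
  wr(edfNum(nsamp / rec@fs, 8))               # record duration (s)
  wr(edfPad(ns, 4))
  nm <- rownames(data); if (is.null(nm)) nm <- sprintf("ch%d", seq_len(ns))
  for (f in list(function(i) edfPad(nm[i], 16),
                 function(i) edfPad("", 80),
                 function(i) edfPad("uV", 8),
                 function(i) edfNum(-physMax[i]),
                 function(i) edfNum(physMax[i]),
                 function(i) edfPad(digMin, 8),
                 function(i) edfPad(digMax, 8),
                 function(i) edfPad("", 80),
                 function(i) edfPad(nsamp, 8),
                 function(i) edfPad("", 32)))
    for (i in seq_len(ns)) wr(f(i))
  for (i in seq_len(ns)) {
    scl <- (digMax - digMin) / (2 * physMax[i])
    dig <- round((data[i, ] + physMax[i]) * scl) + digMin
    writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path
#' @return an \linkS4class{EEGRecording}
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < n)
      stop("truncated EDF header")
    trimws(raw)
  }
  rd(8)                                        # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))                    # samples per record
  fld(32)
  data <- matrix(0, ns, 0)
  out <- vector("list", ns)
  for (i in seq_len(ns)) out[[i]] <- numeric(nRec * spr[i])
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (length(dig) < spr[i]) stop("truncated EDF data")
      phys <- physMin[i] + (dig - digMin[i]) *
        (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  data <- do.call(rbind, out)
  rownames(data) <- labels
  fs <- spr[1] / recDur
  new("EEGRecording", data = data, fs = fs, t0 = 0)
}
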