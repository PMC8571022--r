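#' Write a recording as a BrainVision triplet
#'
#' Writes \code{<base>.vhdr} (INI-style header), \code{<base>.vmrk}
#' (markers) and \code{<base>.eeg} (binary IEEE float32, multiplexed), the
#' standard Brain Products exchange format.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param basePath path without extension.
#' @return the .vhdr path, invisibly.
#' @export
writeBrainVision <- function(recording, basePath) {
  vhdr <- paste0(basePath, ".vhdr")
  vmrk <- paste0(basePath, ".vmrk")
  eeg <- paste0(basePath, ".eeg")
  nm <- basename(basePath)
  C <- nrow(recording@data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", C),
    paste0("SamplingInterval=", format(1e6 / recording@samplingRate,
                                       scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(C), recording@channelNames)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  ), vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording@data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

# Parse a BrainVision INI-style header into a list of section -> key/value.
parseVhdr <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      out[[sec]][[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Honours DataOrientation (MULTIPLEXED / VECTORIZED) and BinaryFormat
#' (IEEE_FLOAT_32 / INT_16 with per-channel resolution scaling).
#'
#' @param vhdrPath path to the .vhdr header.
#' @param positions optional n x 3 electrode positions; defaults to
#'   \code{standardMontage} of the channel count.
#' @return an \linkS4class{EEGRecording}.
#' @export
readBrainVision <- function(vhdrPath, positions = NULL) {
  hdr <- parseVhdr(readLines(vhdrPath, warn = FALSE, encoding = "latin1"))
  ci <- hdr[["Common Infos"]]
  stopIfNot(!is.null(ci), "not a BrainVision header")
  stopIfNot(toupper(ci$DataFormat %||% "BINARY") == "BINARY",
            "only BINARY DataFormat is supported")
  C <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chinfo <- hdr[["Channel Infos"]]
  names <- character(C); res <- rep(1, C)
  for (k in seq_len(C)) {
    parts <- strsplit(chinfo[[paste0("Ch", k)]], ",", fixed = TRUE)[[1]]
    names[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[k] <- as.numeric(parts[3])
  }
  eegPath <- file.path(dirname(vhdrPath), ci$DataFile)
  nbytes <- file.info(eegPath)$size
  con <- file(eegPath, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    nval <- nbytes / 4
    raw <- readBin(con, numeric(), n = nval, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    nval <- nbytes / 2
    raw <- readBin(con, integer(), n = nval, size = 2L, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  S <- length(raw) %/% C
  raw <- raw[seq_len(S * C)]
  X <- if (orient == "MULTIPLEXED") matrix(raw, C, S)
  else if (orient == "VECTORIZED") t(matrix(raw, S, C))
  else stop("unsupported DataOrientation: ", orient, call. = FALSE)
  X <- X * res
  if (is.null(positions)) positions <- standardMontage(C)$positions
  new("EEGRecording", data = X, samplingRate = fs, channelNames = names,
      channelPositions = positions,
      provenance = list(list(step = "read_brainvision", file = vhdrPath)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as EDF
#'
#' Minimal EDF writer (one-second data records, int16 samples scaled to the
#' per-channel physical range); primarily used to round-trip test the
#' reader. Samples beyond a whole number of records are dropped.
#'
#' @param recording an \linkS4class{EEGRecording}; sampling rate must be an
#'   integer.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEDF <- function(recording, path) {
  fs <- recording@samplingRate
  stopIfNot(abs(fs - round(fs)) < 1e-9, "EDF writer needs integer Hz")
  fs <- as.integer(round(fs))
  C <- nrow(recording@data)
  nrec <- ncol(recording@data) %/% fs
  stopIfNot(nrec >= 1, "recording shorter than one EDF record")
  X <- recording@data[, seq_len(nrec * fs), drop = FALSE]
  # symmetric per-channel physical range; scaling uses exactly the values
  # as printed in the 8-char header fields, so read-back is lossless up to
  # 16-bit quantisation
  physStr <- vapply(apply(abs(X), 1, max), function(a)
    sprintf("%.4g", max(a * 1.01, 1e-3)), "")
  physMax <- as.numeric(physStr)
  physMin <- -physMax
  digMin <- -32768L; digMax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) {
    s <- vapply(as.character(x), function(e) {
      e <- substr(e, 1, n)
      paste0(e, strrep(" ", n - nchar(e)))
    }, "", USE.NAMES = FALSE)
    writeBin(charToRaw(paste0(s, collapse = "")), con)
  }
  wr("0", 8); wr("X X X X", 80); wr("Startdate X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (C + 1L)), 8); wr("", 44)
  wr(as.character(nrec), 8); wr("1", 8); wr(as.character(C), 4)
  wr(recording@channelNames, 16)
  wr(rep("AgAgCl electrode", C), 80)
  wr(rep("uV", C), 8)
  wr(paste0("-", physStr), 8); wr(physStr, 8)
  wr(rep(as.character(digMin), C), 8); wr(rep(as.character(digMax), C), 8)
  wr(rep("", C), 80)
  wr(rep(as.character(fs), C), 8)
  wr(rep("", C), 32)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(C)) {
      dig <- as.integer(round((X[c, idx] - physMin[c]) / scale[c]) + digMin)
      writeBin(pmin(pmax(dig, digMin), digMax), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Reads the fixed 256-byte header plus per-signal headers and decodes the
#' int16 data records with physical/digital scaling. Annotation channels are
#' dropped. All retained signals must share one sampling rate.
#'
#' @param path path to the .edf file.
#' @param positions optional electrode positions.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, positions = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  labs <- vapply(seq_len(C), function(i) rd(16), "")
  for (i in seq_len(C)) rd(80)  # transducer
  for (i in seq_len(C)) rd(8)   # unit
  physMin <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(C)) rd(80)  # prefiltering
  nsamp <- vapply(seq_len(C), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(C)) rd(32)
  keep <- !grepl("EDF Annotations", labs, fixed = TRUE)
  stopIfNot(any(keep), "no signal channels in EDF")
  stopIfNot(length(unique(nsamp[keep])) == 1L,
            "signals with differing sampling rates are not supported")
  ns <- nsamp[keep][1]
  fs <- ns / recDur
  scale <- (physMax - physMin) / (digMax - digMin)
  X <- matrix(0, sum(keep), nrec * ns)
  for (r in seq_len(nrec)) {
    col <- ((r - 1L) * ns + 1L):(r * ns)
    ki <- 0L
    for (c in seq_len(C)) {
      dig <- readBin(con, integer(), n = nsamp[c], size = 2L, signed = TRUE,
                     endian = "little")
      if (keep[c]) {
        ki <- ki + 1L
        X[ki, col] <- (dig - digMin[c]) * scale[c] + physMin[c]
      }
    }
  }
  if (is.null(positions)) positions <- standardMontage(sum(keep))$positions
  new("EEGRecording", data = X, samplingRate = fs,
      channelNames = labs[keep], channelPositions = positions,
      provenance = list(list(step = "read_edf", file = path)))
}

#' Read a recording by extension
#'
#' Dispatches to \code{\link{readBrainVision}} (.vhdr) or
#' \code{\link{readEDF}} (.edf).
#'
#' @param path input path.
#' @param positions optional electrode positions.
#' @return an \linkS4class{EEGRecording}.
#' @export
readRecording <- function(path, positions = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vhdr = readBrainVision(path, positions),
         edf = readEDF(path, positions),
         stop("unsupported recording format: .", ext, call. = FALSE))
}
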