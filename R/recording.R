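#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous EEG recording: a channels-by-samples
#' matrix in microvolts, the sampling rate in Hz, channel labels, and the
#' reference description. Time is in seconds with the first sample at t = 0.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz, > 0.
#' @param channels character vector of channel labels, one per row of `data`.
#' @param reference free-text reference description.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, reference = "unknown") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric channels x samples matrix")
  }
  if (!is_scalar_num(fs) || fs <= 0) stopf("`fs` must be a positive number")
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) {
    stopf("length(channels) (%d) != number of data rows (%d)",
          length(channels), nrow(data))
  }
  if (!all(is.finite(data))) stopf("recording contains non-finite samples")
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(x) ncol(x$data) / x$fs

#' Extract one channel as a numeric vector
#' @param x an `eeg_recording`.
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
get_channel <- function(x, channel) {
  i <- match_channel(x$channels, channel)
  x$data[i, ]
}

match_channel <- function(labels, channel) {
  i <- match(tolower(channel), tolower(labels))
  if (is.na(i)) stopf("channel '%s' not found (have: %s)", channel,
                      paste(labels, collapse = ", "))
  i
}

#' Normalize channel labels to the montage's canonical case
#'
#' Case-insensitive match against the 19-label 10-10 montage plus mastoid
#' labels; labels that match are rewritten in canonical case, unknown labels
#' are kept verbatim with a warning.
#'
#' @param labels character vector.
#' @return character vector, same length.
#' @export
normalize_channel_labels <- function(labels) {
  canon <- c(montage_1010()$label, "M1", "M2", "A1", "A2")
  idx <- match(tolower(labels), tolower(canon))
  unknown <- is.na(idx)
  if (any(unknown)) {
    warnf("unknown channel label(s) kept verbatim: %s",
          paste(labels[unknown], collapse = ", "))
  }
  out <- labels
  out[!unknown] <- canon[idx[!unknown]]
  out
}

# ---------------------------------------------------------------- EDF -------

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Writes a single-data-record EDF (16-bit) file. Physical scaling is chosen
#' per channel from the data range, so the round-trip error is bounded by one
#' quantization step of the 16-bit range.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording
  ns <- nrow(x$data)
  nsamp <- ncol(x$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("synthetic", 80),
    pad_field("tmrsleep", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(1, 8),
    pad_field(format(nsamp / x$fs, digits = 7), 8),
    pad_field(ns, 4)
  )
  pmin <- apply(x$data, 1, min)
  pmax <- apply(x$data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  sig <- paste0(
    paste(vapply(x$channels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(vapply(pmax, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(rep(pad_field(-32768, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(nsamp, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((x$data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768)
    dig <- pmin2(pmax2(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

pmin2 <- function(a, b) ifelse(a < b, a, b)
pmax2 <- function(a, b) ifelse(a > b, a, b)

read_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < n) {
      stopf("truncated EDF header in '%s'", path)
    }
    trimws(raw)
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("unparseable EDF header in '%s'", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  expected <- hdr_bytes + 2 * sum(spr) * n_records
  if (sz < expected) stopf("truncated EDF file '%s': %d bytes, expected %d",
                           path, sz, expected)
  data <- matrix(0, ns, spr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs, normalize_channel_labels(labels))
}

# ---------------------------------------------------------- BrainVision -----

#' Write a recording as a BrainVision file triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` with multiplexed
#' IEEE float32 data in microvolts.
#'
#' @param recording an `eeg_recording`.
#' @param path path of the `.vhdr` file (companion files are placed next to it).
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(recording, path) {
  stem <- sub("\\.vhdr$", "", path)
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(recording$data)),
    paste0("SamplingInterval=", format(1e6 / recording$fs, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(recording$channels),
            recording$channels)
  )
  writeLines(hdr, paste0(stem, ".vhdr"), useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  ), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 4, endian = "little")
  invisible(path)
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stopf("BrainVision header '%s' lacks %s", path, key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  if (!any(grepl("Brain Vision Data Exchange Header", lines))) {
    stopf("'%s' is not a BrainVision header file", path)
  }
  fmt <- getval("BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stopf("unsupported BinaryFormat '%s'", fmt)
  orient <- getval("DataOrientation")
  if (orient != "MULTIPLEXED") stopf("unsupported DataOrientation '%s'", orient)
  nch <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  chlines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chlines), ","),
                   function(p) p[1], "")
  datafile <- file.path(dirname(path), getval("DataFile"))
  sz <- file.info(datafile)$size
  if (is.na(sz)) stopf("BrainVision data file '%s' missing", datafile)
  nsamp_total <- sz %/% 4
  if (sz %% 4 != 0 || nsamp_total %% nch != 0) {
    stopf("truncated BrainVision data file '%s'", datafile)
  }
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = nsamp_total, size = 4, endian = "little")
  data <- matrix(vals, nrow = nch)       # multiplexed: channel index fastest
  eeg_recording(data, fs, normalize_channel_labels(labels))
}

# ------------------------------------------------------------- dispatch -----

#' Read an EEG recording (EDF or BrainVision)
#'
#' @param path file path (`.edf`, or a BrainVision `.vhdr`).
#' @param format `"edf"`, `"brainvision"`, or `NULL` to infer from the
#'   file extension.
#' @return an `eeg_recording` with data in microvolts and channel labels
#'   normalized to the 10-10 montage's canonical case.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     stopf("cannot infer format from extension '.%s'", ext))
  }
  switch(match.arg(format, c("edf", "brainvision")),
         edf = read_edf(path),
         brainvision = read_brainvision(path))
}

#' Write an EEG recording (EDF or BrainVision)
#'
#' @param recording an `eeg_recording`.
#' @param path output path (`.edf` or `.vhdr`).
#' @param format `"edf"`, `"brainvision"`, or `NULL` to infer from extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     stopf("cannot infer format from extension '.%s'", ext))
  }
  switch(match.arg(format, c("edf", "brainvision")),
         edf = write_edf(recording, path),
         brainvision = write_brainvision(recording, path))
}
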