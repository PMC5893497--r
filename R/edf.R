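# Minimal European Data Format (EDF) I/O: fixed-layout ASCII header followed
# by 16-bit little-endian sample records. Supports continuous recordings in
# which every signal shares one sampling rate — the geometry this package
# targets (a handful of scalp channels at a common fs).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write a recording as a 16-bit EDF file
#'
#' Emits a standard continuous EDF: one data record per second when the
#' sampling rate is an integer, otherwise a single record spanning the whole
#' session. Amplitudes are mapped linearly onto the full 16-bit digital
#' range per channel, so the round trip through [read_edf()] is exact to
#' about 1/65536 of the channel's amplitude span.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param physical_dim Physical dimension string stored per channel
#'   (default microvolts).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- n_samples(rec)
  nsig <- n_channels(rec)
  if (rec$fs == round(rec$fs) && ns %% rec$fs == 0) {
    spr <- as.integer(rec$fs)          # samples per record
    nrec <- ns %/% spr
    rec_dur <- 1
  } else {
    spr <- ns
    nrec <- 1L
    rec_dur <- ns / rec$fs
  }
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  gain <- (pmax - pmin) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X X",
                  if (is.null(rec$subject_id)) "" else rec$subject_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256L * (1L + nsig), 8),
    edf_pad("", 44),
    edf_num(nrec, 8), edf_num(rec_dur, 8), edf_num(nsig, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", nsig), 80)                      # transducer
  field(rep(physical_dim, nsig), 8)
  field(vapply(pmin, edf_num, character(1), width = 8), 8)
  field(vapply(pmax, edf_num, character(1), width = 8), 8)
  field(rep(edf_num(dmin, 8), nsig), 8)
  field(rep(edf_num(dmax, 8), nsig), 8)
  field(rep("", nsig), 80)                      # prefiltering
  field(rep(edf_num(spr, 8), nsig), 8)
  field(rep("", nsig), 32)                      # reserved

  dig <- matrix(0L, nrow = nsig, ncol = ns)
  for (i in seq_len(nsig))
    dig[i, ] <- as.integer(round((rec$data[i, ] - pmin[i]) / gain[i]) + dmin)
  for (r in seq_len(nrec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(nsig))
      writeBin(dig[i, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Parses the EDF header and sample records and rescales digital values to
#' physical units. All signals must share one sampling rate; annotation
#' channels and per-signal rates are not supported.
#'
#' @param path Path to the EDF file.
#' @return An [eeg_recording()] with `fs` and channel labels taken from the
#'   header.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  take <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- take(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  take(80); take(80); take(8); take(8)
  header_bytes <- as.integer(take(8))
  take(44)
  nrec <- as.integer(take(8))
  rec_dur <- as.numeric(take(8))
  nsig <- as.integer(take(4))
  if (is.na(nsig) || nsig < 1L) stop("EDF header reports no signals")
  fields <- function(width)
    vapply(seq_len(nsig), function(i) take(width), character(1))
  labels <- fields(16)
  fields(80)
  fields(8)
  pmin <- as.numeric(fields(8))
  pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L)
    stop("per-signal sampling rates are not supported")
  spr <- spr[1]
  if (!is.finite(rec_dur) || rec_dur <= 0)
    stop("invalid data-record duration in EDF header")
  fs <- spr / rec_dur
  expected <- 256L * (1L + nsig)
  if (!is.na(header_bytes) && header_bytes != expected)
    stop("EDF header length field (", header_bytes,
         ") does not match signal count")
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(NA_real_, nrow = nsig, ncol = nrec * spr)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      d <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) != spr) stop("truncated EDF data records")
      data[i, (r - 1L) * spr + seq_len(spr)] <-
        (d - dmin[i]) * gain[i] + pmin[i]
    }
  }
  eeg_recording(data, fs = fs, channel_labels = labels)
}
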