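# Minimal EDF (European Data Format, 16-bit) reader/writer.
#
# The format: a 256-byte ASCII fixed-width main header, 256 ASCII bytes per
# signal, then data records of little-endian int16 samples, channel-blocked
# within each record. Physical calibration is linear per channel from the
# (physical min/max, digital min/max) header fields. The writer emits a
# single data record spanning the whole signal, which keeps round trips
# sample-exact for arbitrary lengths.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(signif(x, 6), format = "g", width = 1)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes a 16-bit EDF file with per-channel symmetric physical scaling.
#' Annotations are not embedded in the EDF container; use
#' [write_annotations_csv()] for the sidecar file.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  if (nrow(sig) == 0L) stop_invalid("cannot write an EDF with no channels")
  ns <- nrow(sig)
  nsamp <- ncol(sig)
  srate <- recording$sampling_rate
  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    edf_pad("0", 8),                               # version
    edf_pad("X X X X", 80),                        # patient id
    edf_pad("Startdate X X X X", 80),              # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8),                  # header bytes
    edf_pad("", 44),
    edf_pad(1L, 8),                                # n data records
    edf_num(nsamp / srate, 8),                     # record duration (s)
    edf_pad(ns, 4)
  )
  pmax_ <- pmax(apply(abs(sig), 1L, max), 1e-3)
  # quantize the scale to the value the header field will carry (7 chars,
  # leaving room for the minus sign of the min field) so encoding and
  # decoding use the identical calibration
  # the 0.1% inflation keeps the stored (rounded) scale above every sample
  pstr <- vapply(pmax_ * 1.001, function(v) trimws(edf_num(v, 7)), "")
  pmax_ <- as.numeric(pstr)
  field <- function(values, width)
    paste(vapply(values, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(recording$channel_labels, 16),
    field(rep("", ns), 80),                        # transducer
    field(rep("uV", ns), 8),
    field(paste0("-", pstr), 8),
    field(pstr, 8),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),                        # prefilter
    field(rep(nsamp, ns), 8),
    field(rep("", ns), 32)
  )
  writeBin(charToRaw(hdr), con)
  for (ch in seq_len(ns)) {
    # exact inverse of the linear decode map so round trips stay within
    # half a quantization step
    gain <- 2 * pmax_[ch] / 65535
    dig <- round((sig[ch, ] + pmax_[ch]) / gain) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(raw, offset, width, numeric = FALSE) {
  s <- trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
  if (!numeric) return(s)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop_invalid("EDF format error: non-numeric header field at byte offset ",
                 offset)
  v
}

#' Read an EDF file into an eeg_recording
#'
#' Supports the plain 16-bit EDF layout written by [write_edf()] as well as
#' multi-record files with a common per-channel sampling rate. Channel labels
#' are passed through verbatim.
#'
#' @param path EDF file path.
#' @param annotations optional annotations data frame (e.g. from
#'   [read_annotations_csv()]) to attach.
#' @param timeline_compression nominal seconds per recorded second.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, annotations = NULL, timeline_compression = 1) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 256L)
    stop_invalid("EDF format error: file shorter than the 256-byte header ",
                 "(byte offset ", length(raw), ")")
  header_bytes <- read_edf_field(raw, 184, 8, numeric = TRUE)
  n_records <- read_edf_field(raw, 236, 8, numeric = TRUE)
  rec_dur <- read_edf_field(raw, 244, 8, numeric = TRUE)
  ns <- as.integer(read_edf_field(raw, 252, 4, numeric = TRUE))
  if (ns < 1L) stop_invalid("EDF format error: no signals (byte offset 252)")
  if (header_bytes != 256L * (ns + 1L))
    stop_invalid("EDF format error: header-bytes field inconsistent with ",
                 "signal count (byte offset 184)")
  if (length(raw) < header_bytes)
    stop_invalid("EDF format error: truncated signal headers (byte offset ",
                 length(raw), ")")

  sub <- function(off, width)
    vapply(seq_len(ns) - 1L, function(i)
      trimws(rawToChar(raw[(256L + off * ns + i * width + 1L):
                           (256L + off * ns + (i + 1L) * width)])), "")
  # signal-header block offsets are cumulative widths over all ns signals
  offs <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L)) * ns
  get_block <- function(k, width) {
    base <- 256L + offs[k]
    vapply(seq_len(ns) - 1L, function(i)
      trimws(rawToChar(raw[(base + i * width + 1L):(base + (i + 1L) * width)])),
      "")
  }
  labels <- get_block(1L, 16L)
  phys_min <- as.numeric(get_block(4L, 8L))
  phys_max <- as.numeric(get_block(5L, 8L))
  dig_min <- as.numeric(get_block(6L, 8L))
  dig_max <- as.numeric(get_block(7L, 8L))
  spr <- as.integer(get_block(9L, 8L))
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))))
    stop_invalid("EDF format error: malformed signal header (byte offset 256)")

  n_records <- as.integer(n_records)
  total_vals <- sum(spr) * n_records
  vals <- readBin(raw[(header_bytes + 1L):length(raw)], what = "integer",
                  n = total_vals, size = 2L, endian = "little")
  if (length(vals) < total_vals)
    stop_invalid("EDF format error: data section truncated (byte offset ",
                 length(raw), ")")
  sig <- matrix(0, nrow = ns, ncol = spr[1L] * n_records)
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      idx <- (pos + 1L):(pos + spr[ch])
      sig[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- vals[idx]
      pos <- pos + spr[ch]
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (ch in seq_len(ns))
    sig[ch, ] <- (sig[ch, ] - dig_min[ch]) * gain[ch] + phys_min[ch]
  srate <- spr[1L] / rec_dur
  known <- toupper(labels) %in% toupper(eeg_montage())
  if (!all(known))
    warning("unknown channel labels passed through: ",
            paste(labels[!known], collapse = ", "), call. = FALSE)
  eeg_recording(sig, srate, channel_labels = labels,
                annotations = annotations %||% empty_annotations(),
                timeline_compression = timeline_compression)
}

#' Sidecar CSV export/import for seizure annotations
#'
#' Annotation times are in record coordinates (simulated seconds).
#'
#' @param annotations data frame with `label`, `start_s`, `end_s`,
#'   `channel_scope` (and optionally `animal_id`).
#' @param path CSV path.
#' @return `path` invisibly (write) or the annotations data frame (read).
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
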