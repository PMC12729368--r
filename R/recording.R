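#' Multi-channel EEG recording container
#'
#' Lightweight S3 container for a referenced multi-channel EEG signal, the
#' substrate of all electrophysiological analysis in the package. Signals are
#' stored as a channels-by-samples matrix in microvolts. Time 0 is the start
#' of the record; `start_offset` gives the record start relative to
#' reventilation onset (negative when a pre-asphyxia baseline segment is
#' included). `timeline_compression` records how many nominal seconds each
#' simulated second represents (1 for real recordings), so burden and onset
#' summaries can be reported in nominal hours.
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_labels character vector, one unique label per channel.
#' @param start_offset seconds of record start relative to reventilation
#'   onset (simulated-time seconds).
#' @param annotations data frame with columns `label`, `start_s`, `end_s`,
#'   `channel_scope` (times in record coordinates).
#' @param timeline_compression nominal seconds per simulated second (>= 1).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_labels = NULL,
                          start_offset = 0, annotations = empty_annotations(),
                          timeline_compression = 1) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_invalid("`signal` must be a numeric channels x samples matrix")
  check_positive(sampling_rate, "sampling_rate")
  nch <- nrow(signal)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop_invalid("one channel label per signal row required")
  if (anyDuplicated(channel_labels))
    stop_invalid("channel labels must be unique")
  annotations <- as_annotations(annotations)
  dur <- ncol(signal) / sampling_rate
  if (nrow(annotations) &&
      (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9)))
    stop_invalid("annotations must lie within the record bounds")
  structure(list(
    signal = signal,
    sampling_rate = sampling_rate,
    channel_labels = as.character(channel_labels),
    start_offset = start_offset,
    annotations = annotations,
    timeline_compression = timeline_compression
  ), class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(label = character(), start_s = numeric(), end_s = numeric(),
             channel_scope = character(), stringsAsFactors = FALSE)
}

as_annotations <- function(x) {
  if (is.null(x) || !nrow(as.data.frame(x))) return(empty_annotations())
  x <- as.data.frame(x)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(x)))
    stop_invalid("annotations need columns label, start_s, end_s")
  if (is.null(x$channel_scope)) x$channel_scope <- "generalized"
  if (any(x$end_s < x$start_s)) stop_invalid("annotation end before start")
  x[, c("label", "start_s", "end_s", "channel_scope")]
}

#' Duration of a recording in (simulated) seconds
#' @param recording an [eeg_recording()].
#' @return length in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate
}

#' Standard eight-electrode fronto-parieto-centro-occipital montage
#'
#' Channel labels of the modified neonatal 10-20 montage used for piglet
#' recordings (frontal, central, parietal and occipital leads, both
#' hemispheres).
#' @return character vector of eight labels.
#' @export
eeg_montage <- function() c("Fp1", "Fp2", "C3", "C4", "P3", "P4", "O1", "O2")

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              recording_duration(x)))
  if (x$timeline_compression != 1)
    cat(sprintf(" ~ %.1f nominal h",
                sim_s_to_nominal_h(recording_duration(x),
                                   x$timeline_compression)))
  cat(")\n")
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  annotations:", nrow(x$annotations), "\n")
  invisible(x)
}
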