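# Electrographic seizure detection from spectral-entropy and amplitude
# features. A rhythmic discharge concentrates spectral mass (entropy drops)
# while its amplitude rises well above the ongoing background; epochs where
# both happen, relative to a rolling background estimate, are flagged and
# merged into events.

#' Detection configuration
#'
#' @param window_s detection sub-epoch length in simulated seconds
#'   (default 1; finer than the qEEG grid so short discharges are resolved).
#' @param z_thr entropy criterion: flag when the smoothed entropy z-score
#'   (vs. the rolling background median/MAD) is `<= -z_thr`.
#' @param a_thr amplitude criterion: flag when epoch RMS is `>= a_thr`
#'   times the rolling background RMS.
#' @param smooth_epochs moving-average span (odd) applied to the entropy
#'   series before the z-score; the amplitude criterion stays unsmoothed so
#'   event boundaries remain sharp.
#' @param background_epochs size of the rolling background buffer (trailing
#'   non-flagged, non-suppressed epochs).
#' @param min_background_epochs warm-up before flagging is allowed.
#' @param gap_epochs flagged runs separated by at most this many epochs are
#'   merged into one event.
#' @param min_duration_s events shorter than this are discarded (default 3 s
#'   simulated).
#' @param suppressed_rms_uv isoelectric threshold; suppressed epochs are
#'   never flagged and never enter the background buffer.
#' @return configuration list for [detect_events()].
#' @export
detection_config <- function(window_s = 1, z_thr = 1.25, a_thr = 2,
                             smooth_epochs = 3, background_epochs = 60,
                             min_background_epochs = 15, gap_epochs = 2,
                             min_duration_s = 3, suppressed_rms_uv = 2) {
  check_positive(window_s, "window_s")
  check_positive(z_thr, "z_thr")
  check_positive(a_thr, "a_thr")
  list(window_s = window_s, z_thr = z_thr, a_thr = a_thr,
       smooth_epochs = smooth_epochs, background_epochs = background_epochs,
       min_background_epochs = min_background_epochs,
       gap_epochs = gap_epochs, min_duration_s = min_duration_s,
       suppressed_rms_uv = suppressed_rms_uv)
}

#' Per-epoch seizure-detection feature series
#'
#' Computes, on contiguous detection sub-epochs, the normalized spectral
#' entropy of the channel-averaged PSD (generalized discharges reinforce
#' across channels), the channel-mean RMS amplitude and line length.
#' Suppressed (isoelectric) epochs carry `NA` sentinels for entropy.
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param cfg a [detection_config()].
#' @return data frame: `epoch`, `start_s`, `end_s`, `entropy`, `rms_uv`,
#'   `line_length`, `suppressed`.
#' @export
entropy_feature_series <- function(recording, cfg = detection_config()) {
  eps <- epoch_stream(recording, cfg$window_s, overlap_fraction = 0)
  nch <- nrow(recording$signal)
  out <- eps
  out$entropy <- NA_real_; out$rms_uv <- NA_real_
  out$line_length <- NA_real_; out$suppressed <- FALSE
  for (e in seq_len(nrow(eps))) {
    block <- epoch_samples(recording, eps$start_s[e], cfg$window_s)
    rvals <- apply(block, 1L, rms)
    ll <- mean(apply(block, 1L, function(x) mean(abs(diff(x)))))
    # entropy of the channel-averaged PSD: coherent (generalized) discharge
    # lines reinforce across channels while background noise averages out
    psum <- NULL
    for (ch in seq_len(nch)) {
      psd <- compute_psd(block[ch, ], recording$sampling_rate,
                         segment_s = cfg$window_s)
      if (is.null(psum)) psum <- psd else psum$power <- psum$power + psd$power
    }
    supp <- mean(rvals) < cfg$suppressed_rms_uv
    out$rms_uv[e] <- mean(rvals)
    out$line_length[e] <- ll
    out$entropy[e] <- if (supp) NA_real_ else spectral_entropy(psum)
    out$suppressed[e] <- supp
  }
  out
}

moving_average <- function(x, span) {
  if (span <= 1L) return(x)
  half <- span %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(x[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Detect electrographic seizure events
#'
#' Walks the feature series causally, maintaining a buffer of the most
#' recent background (non-flagged, non-suppressed) epochs. An epoch is
#' flagged when its smoothed entropy falls at least `z_thr` robust standard
#' deviations (median/MAD) below the background AND its raw RMS is at least
#' `a_thr` times the background median RMS. Flagged runs are merged across
#' gaps of at most `gap_epochs` and runs shorter than `min_duration_s`
#' discarded. Each event carries the dominant frequency (PSD argmax over the
#' event interval) and peak amplitude.
#'
#' @param features output of [entropy_feature_series()].
#' @param cfg a [detection_config()].
#' @param recording the recording the features came from (needed for the
#'   dominant-frequency estimate; optional).
#' @return data frame of events: `start_s`, `end_s`, `duration_s`,
#'   `channel_scope`, `dominant_hz`, `peak_amplitude_uv`.
#' @export
detect_events <- function(features, cfg = detection_config(),
                          recording = NULL) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), channel_scope = character(),
                      dominant_hz = numeric(), peak_amplitude_uv = numeric())
  n <- nrow(features)
  if (!n) return(empty)
  ent_s <- moving_average(features$entropy, cfg$smooth_epochs)
  flag <- logical(n)
  buf_ent <- numeric(0); buf_rms <- numeric(0)
  for (i in seq_len(n)) {
    if (features$suppressed[i] || !is.finite(ent_s[i])) next
    admit <- TRUE
    if (length(buf_ent) >= cfg$min_background_epochs) {
      med <- stats::median(buf_ent)
      mad <- stats::mad(buf_ent)
      mad <- max(mad, 0.01)
      z <- (ent_s[i] - med) / mad
      ratio <- features$rms_uv[i] / max(stats::median(buf_rms), 1e-9)
      flag[i] <- (z <= -cfg$z_thr) && (ratio >= cfg$a_thr)
      # amplitude-anomalous epochs stay out of the background buffer even
      # when unflagged, so long episodes cannot contaminate their own
      # reference
      admit <- !flag[i] && ratio < cfg$a_thr
    }
    if (admit) {
      buf_ent <- c(buf_ent, ent_s[i]); buf_rms <- c(buf_rms, features$rms_uv[i])
      if (length(buf_ent) > cfg$background_epochs) {
        buf_ent <- buf_ent[-1L]; buf_rms <- buf_rms[-1L]
      }
    }
  }
  # merge flagged runs across short gaps
  runs <- rle(flag)
  if (length(runs$values) > 2L) {
    idx_end <- cumsum(runs$lengths)
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] && k > 1L && k < length(runs$values) &&
          runs$lengths[k] <= cfg$gap_epochs)
        flag[(idx_end[k] - runs$lengths[k] + 1L):idx_end[k]] <- TRUE
    }
  }
  runs <- rle(flag)
  idx_end <- cumsum(runs$lengths)
  events <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- idx_end[k] - runs$lengths[k] + 1L
    i1 <- idx_end[k]
    start_s <- features$start_s[i0]
    end_s <- features$end_s[i1]
    if (end_s - start_s < cfg$min_duration_s) next
    dom <- NA_real_; peak <- max(features$rms_uv[i0:i1])
    if (!is.null(recording)) {
      block <- epoch_samples(recording, start_s, end_s - start_s)
      psum <- NULL
      for (ch in seq_len(nrow(block))) {
        psd <- compute_psd(block[ch, ], recording$sampling_rate,
                           segment_s = 1)
        psum <- if (is.null(psum)) psd$power else psum + psd$power
        freqs <- psd$frequencies
      }
      dom <- freqs[which.max(psum)]
      peak <- max(abs(block))
    }
    events[[length(events) + 1L]] <- data.frame(
      start_s = start_s, end_s = end_s, duration_s = end_s - start_s,
      channel_scope = "generalized", dominant_hz = dom,
      peak_amplitude_uv = peak)
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

#' Per-animal seizure burden and onset summary
#'
#' Totals are reported in nominal (rescaled) hours using the recording's
#' timeline compression; onset latency is relative to reventilation onset.
#' Animals without events are marked seizure-free with an undefined onset.
#'
#' @param events event table from [detect_events()] (or an annotation table
#'   with `start_s`/`end_s`), non-overlapping.
#' @param animal_id,group identifiers carried into the summary.
#' @param timeline_compression nominal seconds per simulated second.
#' @param reventilation_s record time of reventilation onset (i.e. minus the
#'   recording's `start_offset`; 0 if the record starts at reventilation).
#' @return one-row data frame: `animal_id`, `group`, `event_count`,
#'   `total_duration_h`, `onset_latency_h`, `seizure_free`.
#' @export
summarize_seizures <- function(events, animal_id, group,
                               timeline_compression = 1,
                               reventilation_s = 0) {
  if (nrow(events)) {
    ev <- events[order(events$start_s), , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start_s[-1L] < ev$end_s[-nrow(ev)] - 1e-9))
      stop_invalid("events overlap; summary undefined")
  }
  if (!nrow(events))
    return(data.frame(animal_id = animal_id, group = group, event_count = 0L,
                      total_duration_h = 0, onset_latency_h = NA_real_,
                      seizure_free = TRUE))
  data.frame(
    animal_id = animal_id, group = group, event_count = nrow(events),
    total_duration_h = sim_s_to_nominal_h(sum(events$end_s - events$start_s),
                                          timeline_compression),
    onset_latency_h = sim_s_to_nominal_h(min(events$start_s) -
                                           reventilation_s,
                                         timeline_compression),
    seizure_free = FALSE)
}

#' Group-level seizure incidence, onset and burden profile
#'
#' @param summaries row-bound [summarize_seizures()] outputs (>= 1 animal
#'   per group present in the table).
#' @return data frame per group: `n`, `n_seizing`, `incidence`,
#'   `median_onset_h`, `mean_burden_h`, `sem_burden_h`.
#' @export
group_onset_profile <- function(summaries) {
  out <- do.call(rbind, lapply(split(summaries, summaries$group), function(g) {
    seizing <- !g$seizure_free
    data.frame(
      group = g$group[1L], n = nrow(g), n_seizing = sum(seizing),
      incidence = mean(seizing),
      median_onset_h = if (any(seizing))
        stats::median(g$onset_latency_h[seizing]) else NA_real_,
      mean_burden_h = mean(g$total_duration_h),
      sem_burden_h = stats::sd(g$total_duration_h) / sqrt(nrow(g)))
  }))
  rownames(out) <- NULL
  out
}

#' Detect seizures across a whole cohort bundle
#'
#' Convenience wrapper: bandpass-filters each recording, extracts detection
#' features, detects events and summarizes per animal.
#'
#' @param bundle a [generate_cohort()] bundle.
#' @param cfg a [detection_config()].
#' @return list with `events` (all events with `animal_id`) and `summaries`.
#' @export
detect_cohort_seizures <- function(bundle, cfg = detection_config()) {
  ev_all <- list(); summ <- list()
  for (id in names(bundle$recordings)) {
    rec <- bundle$recordings[[id]]
    grp <- bundle$animals$group[bundle$animals$animal_id == id]
    filt <- eeg_bandpass(rec)
    feats <- entropy_feature_series(filt, cfg)
    ev <- detect_events(feats, cfg, recording = filt)
    if (nrow(ev)) ev_all[[id]] <- cbind(animal_id = id, ev)
    summ[[id]] <- summarize_seizures(ev, id, grp,
                                     rec$timeline_compression,
                                     reventilation_s = -rec$start_offset)
  }
  list(events = if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(), summaries = do.call(rbind, summ))
}
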