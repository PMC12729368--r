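#' Per-animal seizure incidence raster
#'
#' Timeline plot of detected seizure episodes, one row per animal grouped by
#' treatment arm, in nominal hours post-reventilation.
#'
#' @param seizures output of [detect_cohort_seizures()] (list with `events`
#'   and `summaries`).
#' @param animals cohort metadata (`animal_id`, `group`).
#' @param timeline_compression nominal seconds per simulated second; taken
#'   as 1 if the event times are already nominal.
#' @param reventilation_s record time of reventilation onset.
#' @return a ggplot object.
#' @export
plot_seizure_raster <- function(seizures, animals, timeline_compression = NULL,
                                reventilation_s = 0) {
  ev <- seizures$events
  comp <- timeline_compression %||%
    attr(seizures, "timeline_compression") %||% 1
  ord <- animals[order(animals$group, animals$animal_id), ]
  ord$y <- seq_len(nrow(ord))
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_continuous(breaks = ord$y, labels = ord$animal_id) +
    ggplot2::labs(x = "hours post-reventilation", y = NULL,
                  title = "Electrographic seizure raster") +
    ggplot2::theme_minimal()
  if (is.data.frame(ev) && nrow(ev)) {
    ev <- merge(ev, ord[, c("animal_id", "y", "group")], by = "animal_id")
    ev$start_h <- sim_s_to_nominal_h(ev$start_s - reventilation_s, comp)
    ev$end_h <- sim_s_to_nominal_h(ev$end_s - reventilation_s, comp)
    p <- p + ggplot2::geom_segment(
      data = ev,
      ggplot2::aes(x = .data$start_h, xend = .data$end_h, y = .data$y,
                   yend = .data$y, colour = .data$group),
      linewidth = 3)
  }
  p
}

#' Group-average PSD overlay with spectral-edge markers
#'
#' Averages the terminal-portion PSD across channels and animals of each
#' group and overlays the three curves with vertical lines at each group's
#' spectral edge frequency.
#'
#' @param bundle a [generate_cohort()] bundle.
#' @param edge SEF power fraction (default 0.95).
#' @param tail_fraction final fraction of each record to average (default
#'   the last 10%, emulating end-of-observation PSDs).
#' @return a ggplot object.
#' @export
plot_psd_sef <- function(bundle, edge = 0.95, tail_fraction = 0.1) {
  rows <- list(); sefs <- list()
  for (grp in unique(bundle$animals$group)) {
    ids <- bundle$animals$animal_id[bundle$animals$group == grp]
    acc <- NULL; freqs <- NULL
    for (id in ids) {
      rec <- bundle$recordings[[id]]
      dur <- recording_duration(rec)
      start <- (1 - tail_fraction) * dur
      block <- epoch_samples(rec, start, dur - start)
      for (ch in seq_len(nrow(block))) {
        psd <- compute_psd(block[ch, ], rec$sampling_rate)
        acc <- if (is.null(acc)) psd$power else acc + psd$power
        freqs <- psd$frequencies
      }
    }
    if (is.null(acc)) next
    avg <- acc / (length(ids) * nrow(bundle$recordings[[ids[1]]]$signal))
    rows[[grp]] <- data.frame(group = grp, frequency_hz = freqs, power = avg)
    sefs[[grp]] <- data.frame(
      group = grp,
      sef_hz = spectral_edge_frequency(list(frequencies = freqs,
                                            power = avg), edge))
  }
  df <- do.call(rbind, rows)
  sf <- do.call(rbind, sefs)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_hz, .data$power,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = sf,
                        ggplot2::aes(xintercept = .data$sef_hz,
                                     colour = .data$group),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(mu*V^2/Hz)),
                  title = "Group-average PSD with spectral edge") +
    ggplot2::theme_minimal()
}
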