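#' Welch power spectral density with a Gaussian taper
#'
#' Estimates a one-sided PSD over the analysis band by Welch's method:
#' the epoch is split into overlapping sub-segments, each demeaned, tapered
#' with a Gaussian window whose length equals `shape_k` standard deviations
#' (kernel size 3-5, default 4), periodogram-transformed and averaged.
#' Scaling compensates the taper power so the integrated PSD matches the
#' time-domain variance of the band-limited signal.
#'
#' @param x numeric vector, one channel of one epoch (microvolts).
#' @param sampling_rate Hz.
#' @param fmin,fmax analysis band edges in Hz (grid restricted to
#'   `[fmin, fmax]`).
#' @param segment_s Welch sub-segment length in seconds; defaults to
#'   `min(4, length(x)/sampling_rate)`.
#' @param overlap fractional sub-segment overlap (default 0.5).
#' @param shape_k Gaussian kernel size: window length = `shape_k` sigma.
#' @return `spectral_estimate` object: list with `frequencies` (Hz),
#'   `power` (uV^2/Hz), `df` (bin width), `n_segments`, `suppressed` flag
#'   (all-zero input), and the window descriptor.
#' @export
compute_psd <- function(x, sampling_rate, fmin = 1, fmax = 30,
                        segment_s = NULL, overlap = 0.5, shape_k = 4) {
  check_positive(sampling_rate, "sampling_rate")
  n <- length(x)
  segment_s <- segment_s %||% min(4, n / sampling_rate)
  nseg <- max(8L, round(segment_s * sampling_rate))
  if (n < nseg)
    stop_invalid("epoch shorter than one Welch segment (", nseg, " samples)")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  i <- seq_len(nseg) - 1L
  sigma <- nseg / shape_k
  w <- exp(-0.5 * ((i - (nseg - 1) / 2) / sigma)^2)
  scale <- 1 / (sampling_rate * sum(w^2))
  nfreq <- floor(nseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 * scale
    # one-sided: double everything except DC (and Nyquist for even nseg)
    sp[-1L] <- sp[-1L] * 2
    if (nseg %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  pwr <- acc / length(starts)
  freqs <- (seq_len(nfreq) - 1L) * sampling_rate / nseg
  keep <- freqs >= fmin & freqs <= fmax
  structure(list(
    frequencies = freqs[keep],
    power = pwr[keep],
    df = sampling_rate / nseg,
    n_segments = length(starts),
    suppressed = all(x == 0),
    window = list(shape = "gaussian", length_s = nseg / sampling_rate,
                  shape_k = shape_k)
  ), class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins over %.2f-%.2f Hz (df = %.3f), %d segment(s)%s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$df, x$n_segments, if (x$suppressed) " [suppressed]" else ""))
  invisible(x)
}

psd_total_power <- function(psd) sum(psd$power) * psd$df

#' Spectral edge frequency
#'
#' The smallest grid frequency below which at least `edge` (default 95%) of
#' the total band-limited power resides. Computed on the discrete grid
#' without interpolation. Zero total power (suppressed epoch) yields `NA`.
#'
#' @param psd a `spectral_estimate` (or list with `frequencies`, `power`).
#' @param edge power fraction in (0, 1]; default 0.95.
#' @return frequency in Hz, or `NA_real_` for a powerless spectrum.
#' @export
spectral_edge_frequency <- function(psd, edge = 0.95) {
  if (edge <= 0 || edge > 1) stop_invalid("`edge` must be in (0, 1]")
  total <- sum(psd$power)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  cum <- cumsum(psd$power)
  psd$frequencies[which(cum >= edge * total - 1e-12 * total)[1L]]
}

#' Normalized Shannon spectral entropy
#'
#' `H = -sum(p_i log p_i) / log N` where `p_i` is the power in grid bin `i`
#' divided by the total power over the `N` bins of the analysis band.
#' Unitless in `[0, 1]`: 0 for a single-bin point mass, 1 for a flat
#' spectrum; higher values indicate power spread more evenly across
#' frequencies. Scale-invariant and log-base-invariant. Zero total power
#' yields `NA`.
#'
#' @param psd a `spectral_estimate` (or list with `power`).
#' @return entropy in `[0, 1]`, or `NA_real_` for a powerless spectrum.
#' @export
spectral_entropy <- function(psd) {
  p <- psd$power
  total <- sum(p)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  n <- length(p)
  if (n < 2L) return(0)
  p <- p / total
  p <- p[p > 0]
  -sum(p * log(p)) / log(n)
}

#' Band powers from a spectral estimate
#'
#' Integrates the PSD over each configured band (half-open intervals
#' `(low, high]` to avoid double-counting shared edges).
#'
#' @param psd a `spectral_estimate`.
#' @param bands named list of band edges as from [qeeg_bands()].
#' @return named numeric vector of band powers (uV^2).
#' @export
band_powers <- function(psd, bands = qeeg_bands()) {
  vapply(bands, function(b) {
    lo <- b[1]; hi <- b[2]
    sel <- if (lo <= min(psd$frequencies)) {
      psd$frequencies >= lo & psd$frequencies <= hi
    } else psd$frequencies > lo & psd$frequencies <= hi
    sum(psd$power[sel]) * psd$df
  }, numeric(1))
}

#' Normalize a metric series to its pre-asphyxia baseline
#'
#' Divides each value by the mean of the series over the baseline interval,
#' so the baseline maps to 1 by construction. For grouped data frames the
#' normalization is applied within each combination of the grouping columns
#' (e.g. channel x band).
#'
#' @param values numeric vector of per-epoch values, or a data frame.
#' @param epoch_start_s epoch start times (same length as `values`); for the
#'   data-frame method, the name of the time column.
#' @param baseline_interval `c(start_s, end_s)` of the pre-asphyxia baseline
#'   in record coordinates; must contain at least one epoch.
#' @param value_col,by for the data-frame method: value column name and
#'   grouping column names.
#' @return normalized vector, or the data frame with a `<value_col>_norm`
#'   column added.
#' @export
normalize_to_baseline <- function(values, epoch_start_s, baseline_interval,
                                  value_col = NULL, by = NULL) {
  if (is.data.frame(values)) {
    df <- values
    tcol <- epoch_start_s
    key <- if (length(by)) interaction(df[by], drop = TRUE) else
      factor(rep(1, nrow(df)))
    out <- rep(NA_real_, nrow(df))
    for (lev in levels(key)) {
      idx <- which(key == lev)
      out[idx] <- normalize_to_baseline(df[[value_col]][idx], df[[tcol]][idx],
                                        baseline_interval)
    }
    df[[paste0(value_col, "_norm")]] <- out
    return(df)
  }
  if (length(baseline_interval) != 2L ||
      baseline_interval[2] <= baseline_interval[1])
    stop_invalid("`baseline_interval` must be c(start, end) with end > start")
  inb <- epoch_start_s >= baseline_interval[1] &
    epoch_start_s < baseline_interval[2]
  if (!any(inb)) stop_invalid("baseline interval contains no epochs")
  ref <- mean(values[inb], na.rm = TRUE)
  if (!is.finite(ref) || ref == 0)
    stop_invalid("zero or undefined baseline power; normalization undefined")
  values / ref
}

#' Per-channel, per-epoch quantitative EEG time course
#'
#' Epochs the recording, estimates a PSD per channel and epoch, and derives
#' the qEEG markers: RMS amplitude, spectral edge frequency, normalized
#' spectral entropy and band powers. Epochs with RMS below
#' `suppressed_rms_uv` are flagged suppressed (isoelectric) and their
#' spectral markers set to `NA` so they drop out of group summaries.
#'
#' @param recording a bandpass-filtered [eeg_recording()].
#' @param window_s epoch length in simulated seconds (default 30).
#' @param overlap_fraction epoch overlap (default 0.5).
#' @param bands band partition, see [qeeg_bands()].
#' @param suppressed_rms_uv isoelectric threshold in microvolts (default 2).
#' @param edge SEF power fraction (default 0.95).
#' @param psd_segment_s Welch sub-segment length passed to [compute_psd()].
#' @return data frame: `channel`, `epoch`, `start_s`, `rms_uv`, `sef_hz`,
#'   `entropy`, `suppressed`, one `power_<band>` column per band.
#' @export
qeeg_timecourse <- function(recording, window_s = 30, overlap_fraction = 0.5,
                            bands = qeeg_bands(), suppressed_rms_uv = 2,
                            edge = 0.95, psd_segment_s = NULL) {
  eps <- epoch_stream(recording, window_s, overlap_fraction)
  nch <- nrow(recording$signal)
  rows <- vector("list", nrow(eps) * nch)
  k <- 0L
  for (e in seq_len(nrow(eps))) {
    block <- epoch_samples(recording, eps$start_s[e], window_s)
    for (ch in seq_len(nch)) {
      x <- block[ch, ]
      r <- rms(x)
      supp <- r < suppressed_rms_uv
      psd <- compute_psd(x, recording$sampling_rate,
                         segment_s = psd_segment_s)
      bp <- band_powers(psd, bands)
      k <- k + 1L
      rows[[k]] <- data.frame(
        channel = recording$channel_labels[ch], epoch = e,
        start_s = eps$start_s[e], rms_uv = r,
        sef_hz = if (supp) NA_real_ else spectral_edge_frequency(psd, edge),
        entropy = if (supp) NA_real_ else spectral_entropy(psd),
        suppressed = supp,
        t(bp))
    }
  }
  out <- do.call(rbind, rows)
  for (bn in names(bands))
    names(out)[names(out) == bn] <- paste0("power_", bn)
  rownames(out) <- NULL
  out
}

#' Group-level qEEG summary across a cohort
#'
#' Aggregates per-animal qEEG markers (mean over channels, then over
#' animals within treatment group), either from the terminal analysis epoch
#' (default; mirrors end-of-observation comparisons) or time-averaged over
#' the whole record. Suppressed epochs are excluded.
#'
#' @param qeeg_tables named list (by animal id) of [qeeg_timecourse()]
#'   outputs.
#' @param groups named character vector mapping animal id to group label.
#' @param mode `"terminal"` (last epoch with any unsuppressed channel) or
#'   `"timeaverage"`.
#' @return list with `animals` (per-animal SEF/entropy) and `groups`
#'   (group means +/- SEM).
#' @export
qeeg_group_summary <- function(qeeg_tables, groups,
                               mode = c("terminal", "timeaverage")) {
  mode <- match.arg(mode)
  per_animal <- lapply(names(qeeg_tables), function(id) {
    tab <- qeeg_tables[[id]]
    ok <- tab[!tab$suppressed & is.finite(tab$sef_hz), , drop = FALSE]
    if (!nrow(ok)) return(data.frame(animal_id = id, group = groups[[id]],
                                     sef_hz = NA_real_, entropy = NA_real_))
    if (mode == "terminal") ok <- ok[ok$epoch == max(ok$epoch), , drop = FALSE]
    data.frame(animal_id = id, group = groups[[id]],
               sef_hz = mean(ok$sef_hz), entropy = mean(ok$entropy))
  })
  animals <- do.call(rbind, per_animal)
  sem <- function(x) stats::sd(x) / sqrt(sum(is.finite(x)))
  groups_df <- do.call(rbind, lapply(split(animals, animals$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g),
               sef_hz = mean(g$sef_hz, na.rm = TRUE),
               sef_sem = sem(g$sef_hz[is.finite(g$sef_hz)]),
               entropy = mean(g$entropy, na.rm = TRUE),
               entropy_sem = sem(g$entropy[is.finite(g$entropy)]))))
  rownames(groups_df) <- NULL
  list(animals = animals, groups = groups_df)
}
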