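#' Default per-group seizure-simulation parameters
#'
#' Per-arm electrographic-seizure structure: probability that an animal
#' seizes at all, the onset window (hours post-reventilation), and the
#' per-animal total-burden distribution, Gamma with the stated mean and SD
#' (mean/SEM pairs 3.4 +/- 1.0 h over n = 6 and 3.1 +/- 0.7 h over n = 8
#' give per-animal SDs of ~2.45 and ~1.98 h). Defaults: the hypothermia arm
#' never seizes; the hydrogen arm seizes with a delayed onset window
#' relative to normothermia; episodes are clustered after hour 24.
#'
#' @param probability_any named per-group probability of any seizure.
#' @param onset_window_h named list of `c(earliest, latest)` onset hours.
#' @param burden_mean_h,burden_sd_h per-group total-burden Gamma moments.
#' @param episode_rate extra-episode Poisson rate (episode count =
#'   1 + Poisson(rate)).
#' @param discharge_hz spike-and-wave repetition rate (default 10 Hz).
#' @param amplitude_gain episode amplitude over local background RMS.
#' @return parameter list for [cohort_spec()].
#' @export
seizure_params <- function(
    probability_any = c(`A-NT` = 5 / 6, `A-H2` = 1, `A-TH` = 0),
    onset_window_h = list(`A-NT` = c(24, 34), `A-H2` = c(30, 44),
                          `A-TH` = c(30, 44)),
    burden_mean_h = c(`A-NT` = 3.4, `A-H2` = 3.1, `A-TH` = 0),
    burden_sd_h = c(`A-NT` = 1.0 * sqrt(6), `A-H2` = 0.7 * sqrt(8),
                    `A-TH` = 0),
    episode_rate = 2,
    discharge_hz = 10,
    amplitude_gain = 4) {
  check_probability(probability_any, "probability_any")
  check_positive(discharge_hz, "discharge_hz")
  check_positive(amplitude_gain, "amplitude_gain")
  list(probability_any = probability_any, onset_window_h = onset_window_h,
       burden_mean_h = burden_mean_h, burden_sd_h = burden_sd_h,
       episode_rate = episode_rate, discharge_hz = discharge_hz,
       amplitude_gain = amplitude_gain)
}

#' Specification of a synthetic three-arm cohort
#'
#' Bundles every generator parameter: group sizes (defaults 6/8/8), the
#' timeline compression factor (nominal seconds represented by each
#' simulated second; 480 turns the 48 h observation into 360 s of signal),
#' background-EEG parameters with per-group spectral exponents (the
#' hydrogen arm recovers a flatter, more complex spectrum; the hypothermia
#' arm a steeper, more suppressed one), seizure structure, VEP parameters
#' with per-group latency offsets (hypothermia shortens P100 latency), and
#' pathology parameters.
#'
#' @param n_per_group named integer vector of animals per arm.
#' @param seed integer master seed; the cohort is a deterministic function
#'   of `(spec, seed)`.
#' @param timeline_compression nominal seconds per simulated second (>= 1).
#' @param duration_h,baseline_h nominal observation period and pre-asphyxia
#'   baseline length in hours.
#' @param sampling_rate,n_channels signal layout.
#' @param background list: `baseline_amplitude` (uV), `isoelectric_h`,
#'   `recovery_tau_h`, per-group `alpha` and `amplitude_scale`.
#' @param seizures a [seizure_params()] list.
#' @param vep a [vep_params()] list plus per-group `latency_offset_ms`.
#' @param pathology a [pathology_params()] list.
#' @return `cohort_spec` object.
#' @export
cohort_spec <- function(
    n_per_group = c(`A-NT` = 6, `A-H2` = 8, `A-TH` = 8),
    seed = 1L,
    timeline_compression = 480,
    duration_h = 48,
    baseline_h = 1,
    sampling_rate = 256,
    n_channels = 8,
    background = list(
      baseline_amplitude = 25,
      isoelectric_h = 1,
      recovery_tau_h = 8,
      alpha = c(`A-NT` = 2.0, `A-H2` = 1.6, `A-TH` = 2.6),
      amplitude_scale = c(`A-NT` = 1, `A-H2` = 1, `A-TH` = 0.8)),
    seizures = seizure_params(),
    vep = c(vep_params(),
            list(latency_offset_ms = c(`A-NT` = 0, `A-H2` = -4,
                                       `A-TH` = -15))),
    pathology = pathology_params()) {
  if (is.null(names(n_per_group)) ||
      !setequal(names(n_per_group), group_labels()))
    stop_invalid("`n_per_group` must be named with the three group labels")
  if (any(n_per_group < 0)) stop_invalid("group sizes must be non-negative")
  if (timeline_compression < 1)
    stop_invalid("`timeline_compression` must be >= 1")
  check_positive(duration_h, "duration_h")
  structure(list(
    n_per_group = n_per_group[group_labels()], seed = as.integer(seed),
    timeline_compression = timeline_compression, duration_h = duration_h,
    baseline_h = baseline_h, sampling_rate = sampling_rate,
    n_channels = n_channels, background = background, seizures = seizures,
    vep = vep, pathology = pathology), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s animals, %g h at compression %g, seed %d\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = " "),
              x$duration_h, x$timeline_compression, x$seed))
  invisible(x)
}

# Sample one animal's seizure schedule (nominal hours): onset, episode
# durations and start times. Episodes are non-overlapping with a minimum
# inter-episode gap; fragments shorter than `min_episode_h` are merged into
# the largest episode so the injected total equals the drawn burden exactly.
sample_seizure_schedule <- function(sz, group, duration_h, compression) {
  if (stats::runif(1) >= sz$probability_any[[group]] ||
      sz$burden_mean_h[[group]] <= 0)
    return(NULL)
  m <- sz$burden_mean_h[[group]]; s <- sz$burden_sd_h[[group]]
  burden <- if (s > 0)
    stats::rgamma(1, shape = (m / s)^2, scale = s^2 / m) else m
  min_episode_h <- 4 * compression / 3600   # >= 4 simulated seconds
  min_gap_h <- 6 * compression / 3600
  burden <- max(burden, min_episode_h)
  margin_h <- duration_h - 0.5
  n_ep <- 1L + stats::rpois(1, sz$episode_rate)
  d <- burden * rdirichlet1(rep(1, n_ep))
  while (length(d) > 1L && min(d) < min_episode_h) {
    i <- which.min(d); j <- which.max(d[-i])
    j <- which(seq_along(d) != i)[j]
    d[j] <- d[j] + d[i]; d <- d[-i]
  }
  n_ep <- length(d)
  w <- sz$onset_window_h[[group]]
  onset <- stats::runif(1, w[1], w[2])
  required <- sum(d) + (n_ep - 1) * min_gap_h
  onset <- min(onset, margin_h - required)
  onset <- max(onset, 1)
  if (margin_h - onset < required) {       # burden larger than available span
    scale <- (margin_h - onset - (n_ep - 1) * min_gap_h) / sum(d)
    d <- d * scale
  }
  extra <- (margin_h - onset) - required
  pad <- extra * rdirichlet1(rep(1, n_ep))  # slack after each episode
  starts <- numeric(n_ep)
  t <- onset
  for (k in seq_len(n_ep)) {
    starts[k] <- t
    t <- t + d[k] + min_gap_h + pad[k]
  }
  data.frame(start_h = starts, duration_h = d)
}

#' Generate a full synthetic cohort bundle
#'
#' Deterministic under `(spec, seed)`: simulates, for every animal, the
#' post-asphyxia EEG (background recovery plus group-structured
#' spike-and-wave seizures with exact interval annotations), the flash-VEP
#' trial set, the temperature protocol schedule, and the neuropathology
#' observations, plus group metadata.
#'
#' @param spec a [cohort_spec()].
#' @return list with `animals` (metadata), `recordings` (named list of
#'   [eeg_recording()]s), `annotations` (all injected seizure intervals with
#'   `animal_id`), `vep` (named list of trial bundles), `schedules`,
#'   `pathology` (`counts` + `fields`), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_invalid("need a cohort_spec")
  set.seed(spec$seed)
  comp <- spec$timeline_compression
  groups <- rep(group_labels(), times = spec$n_per_group)
  ids <- sprintf("%s-%02d", gsub("A-", "", groups),
                 unlist(lapply(spec$n_per_group, seq_len)))
  animals <- data.frame(animal_id = ids, group = groups,
                        stringsAsFactors = FALSE)
  animal_seeds <- sample.int(2^31 - 2, nrow(animals) * 2L)

  dur_s <- nominal_h_to_sim_s(spec$duration_h, comp)
  base_s <- nominal_h_to_sim_s(spec$baseline_h, comp)
  recordings <- list(); veps <- list(); ann_all <- list()
  for (i in seq_len(nrow(animals))) {
    grp <- animals$group[i]
    set.seed(animal_seeds[i])
    bg <- spec$background
    params <- background_params(
      baseline_amplitude = bg$baseline_amplitude * bg$amplitude_scale[[grp]],
      isoelectric_duration_s = nominal_h_to_sim_s(bg$isoelectric_h, comp),
      recovery_tau_s = nominal_h_to_sim_s(bg$recovery_tau_h, comp),
      alpha = bg$alpha[[grp]],
      baseline_duration_s = base_s,
      sampling_rate = spec$sampling_rate,
      n_channels = spec$n_channels)
    rec <- generate_background(dur_s, params, timeline_compression = comp)
    sched <- sample_seizure_schedule(spec$seizures, grp, spec$duration_h,
                                     comp)
    if (!is.null(sched)) {
      for (k in seq_len(nrow(sched))) {
        rec <- inject_seizure(
          rec,
          start_s = base_s + nominal_h_to_sim_s(sched$start_h[k], comp),
          duration_s = nominal_h_to_sim_s(sched$duration_h[k], comp),
          discharge_hz = spec$seizures$discharge_hz,
          amplitude_gain = spec$seizures$amplitude_gain)
      }
    }
    recordings[[animals$animal_id[i]]] <- rec
    if (nrow(rec$annotations))
      ann_all[[animals$animal_id[i]]] <-
        cbind(animal_id = animals$animal_id[i], rec$annotations)

    set.seed(animal_seeds[nrow(animals) + i])
    vp <- spec$vep
    vp$p100_latency_ms <- vp$p100_latency_ms + vp$latency_offset_ms[[grp]]
    vp$latency_offset_ms <- NULL
    veps[[animals$animal_id[i]]] <- generate_vep_trials(do.call(vep_params, vp))
  }
  schedules <- lapply(stats::setNames(group_labels(), group_labels()),
                      generate_protocol_schedule,
                      duration_h = spec$duration_h)
  set.seed(animal_seeds[1L] %% 2147483L + 7L)
  pathology <- generate_pathology(animals, spec$pathology)
  list(animals = animals, recordings = recordings,
       annotations = if (length(ann_all)) do.call(rbind, ann_all) else
         cbind(animal_id = character(0), empty_annotations()),
       vep = veps, schedules = schedules, pathology = pathology, spec = spec)
}
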