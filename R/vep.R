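#' Average stimulus-locked VEP trials
#'
#' Subtracts each trial's pre-stimulus baseline mean, then averages
#' pointwise across trials. Uncorrelated noise in the grand average scales
#' as 1/sqrt(n) of the single-trial noise.
#'
#' @param trials numeric matrix, trials x samples (uV), or a trial bundle
#'   from [generate_vep_trials()].
#' @param times_ms peri-stimulus sample times in ms (0 = flash); taken from
#'   the bundle when `trials` is one.
#' @param baseline_window_ms pre-stimulus baseline `c(from, to)` in ms
#'   (default -50 to 0).
#' @return `vep_average` object: list with `grand_average`, `times_ms`,
#'   `n_trials`.
#' @export
average_trials <- function(trials, times_ms = NULL,
                           baseline_window_ms = c(-50, 0)) {
  if (is.list(trials) && !is.null(trials$trials)) {
    times_ms <- times_ms %||% trials$times_ms
    trials <- trials$trials
  }
  if (!is.matrix(trials) || nrow(trials) < 1L)
    stop_invalid("`trials` must be a trials x samples matrix with >= 1 row")
  if (is.null(times_ms) || length(times_ms) != ncol(trials))
    stop_invalid("`times_ms` must match the trial epoch length")
  base_idx <- times_ms >= baseline_window_ms[1] &
    times_ms <= baseline_window_ms[2]
  if (!any(base_idx)) stop_invalid("baseline window contains no samples")
  centered <- trials - rowMeans(trials[, base_idx, drop = FALSE])
  structure(list(grand_average = colMeans(centered), times_ms = times_ms,
                 n_trials = nrow(trials)), class = "vep_average")
}

#' Extract the P100 component from a grand-average VEP
#'
#' Latency is the time of the maximum positive deflection within the search
#' window, refined by parabolic sub-sample interpolation around the discrete
#' peak; amplitude is the (interpolated) peak relative to the pre-stimulus
#' baseline mean. A window with no positive deflection is flagged as an
#' absent response.
#'
#' @param avg a `vep_average` (or list with `grand_average`, `times_ms`,
#'   `n_trials`).
#' @param search_window_ms P100 search window (default 70-150 ms).
#' @param baseline_window_ms baseline reference window (default -50-0 ms).
#' @return `vep_result`: one-row data frame with `n_trials`, `latency_ms`,
#'   `amplitude_uv`, `absent_response`.
#' @export
extract_p100 <- function(avg, search_window_ms = c(70, 150),
                         baseline_window_ms = c(-50, 0)) {
  t_ms <- avg$times_ms
  if (search_window_ms[1] < min(t_ms) || search_window_ms[2] > max(t_ms))
    stop_invalid("search window outside the epoch")
  base <- mean(avg$grand_average[t_ms >= baseline_window_ms[1] &
                                   t_ms <= baseline_window_ms[2]])
  win <- which(t_ms >= search_window_ms[1] & t_ms <= search_window_ms[2])
  rel <- avg$grand_average[win] - base
  if (max(rel) <= 0)
    return(data.frame(n_trials = avg$n_trials %||% NA_integer_,
                      latency_ms = NA_real_, amplitude_uv = NA_real_,
                      absent_response = TRUE))
  k <- win[which.max(rel)]
  lat <- t_ms[k]; amp <- avg$grand_average[k] - base
  # parabolic sub-sample interpolation around the discrete peak
  if (k > 1L && k < length(t_ms)) {
    y0 <- avg$grand_average[k - 1L]; y1 <- avg$grand_average[k]
    y2 <- avg$grand_average[k + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) {
      delta <- 0.5 * (y0 - y2) / denom
      if (abs(delta) <= 0.5) {
        lat <- lat + delta * (t_ms[k + 1L] - t_ms[k])
        amp <- y1 - 0.25 * (y0 - y2) * delta - base
      }
    }
  }
  data.frame(n_trials = avg$n_trials %||% NA_integer_,
             latency_ms = lat, amplitude_uv = amp,
             absent_response = FALSE)
}

#' Compare P100 latency and amplitude across treatment groups
#'
#' Per-group means +/- SEM with the statistical comparison delegated to the
#' group-stats layer (one-way ANOVA with Tukey HSD on each measure).
#'
#' @param results data frame with `animal_id`, `group`, `latency_ms`,
#'   `amplitude_uv` (one row per animal; absent responses excluded).
#' @param alpha significance level for the pairwise table.
#' @return list with `table` (per-group summaries) and `tests` (named list
#'   of `test_result` objects for latency and amplitude).
#' @export
group_vep_compare <- function(results, alpha = 0.05) {
  results <- results[!is.na(results$latency_ms), , drop = FALSE]
  if (length(unique(results$group)) < 2L)
    stop_invalid("need >= 2 groups to compare")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tab <- do.call(rbind, lapply(split(results, results$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g),
               latency_ms = mean(g$latency_ms),
               latency_sem = sem(g$latency_ms),
               amplitude_uv = mean(g$amplitude_uv),
               amplitude_sem = sem(g$amplitude_uv))))
  rownames(tab) <- NULL
  tests <- list(
    latency = anova_groups(split(results$latency_ms, results$group),
                           alpha = alpha),
    amplitude = anova_groups(split(results$amplitude_uv, results$group),
                             alpha = alpha))
  list(table = tab, tests = tests)
}

#' VEP analysis for a whole cohort bundle
#'
#' Averages each animal's trials and extracts P100 measures.
#'
#' @param bundle a [generate_cohort()] bundle.
#' @return data frame: `animal_id`, `group`, `n_trials`, `latency_ms`,
#'   `amplitude_uv`, `absent_response`.
#' @export
cohort_vep_results <- function(bundle) {
  out <- lapply(names(bundle$vep), function(id) {
    avg <- average_trials(bundle$vep[[id]])
    res <- extract_p100(avg)
    cbind(animal_id = id,
          group = bundle$animals$group[bundle$animals$animal_id == id], res)
  })
  do.call(rbind, out)
}
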