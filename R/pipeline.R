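# End-to-end orchestration: simulate -> preprocess -> qEEG -> seizures ->
# VEP -> pathology -> group statistics, from a single validated config.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "neoqeeg-run",
    simulate = TRUE,
    cohort = list(),          # overrides forwarded to cohort_spec()
    qeeg = list(window_s = NULL, overlap_fraction = 0.5, edge = 0.95,
                suppressed_rms_uv = 2,
                bands = lapply(qeeg_bands(), identity),
                mode = "terminal"),
    detection = list(window_s = 1, z_thr = 1.25, a_thr = 2, smooth_epochs = 3,
                     background_epochs = 60, min_background_epochs = 15,
                     gap_epochs = 2, min_duration_s = 3,
                     suppressed_rms_uv = 2),
    vep = list(search_window_ms = c(70, 150),
               baseline_window_ms = c(-50, 0)),
    stats = list(alpha = 0.05, dunn_adjust = "none")
  )
}

merge_config <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, paste0("unknown config key: ", full))
      next
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])) && key != "cohort" &&
        key != "bands") {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full,
                                      errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills in every default,
#' rejects unknown keys and invalid values (aggregated into one error), and
#' returns the fully resolved configuration.
#'
#' @param config YAML path, nested list, or `NULL` (pure defaults).
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  if (!is.list(config)) stop_invalid("config must be a list or YAML file")
  errors <- new.env()
  errors$msgs <- character()
  cfg <- merge_config(default_config(), config, "", errors)
  bands <- cfg$qeeg$bands
  edges <- unlist(bands, use.names = FALSE)
  if (any(vapply(bands, function(b) b[2] <= b[1], TRUE)) ||
      any(diff(vapply(bands, `[`, 0, 1)) <= 0))
    errors$msgs <- c(errors$msgs,
                     "qeeg.bands: band edges must be increasing")
  if (!is.null(cfg$cohort$seizures$probability_any)) {
    p <- unlist(cfg$cohort$seizures$probability_any)
    if (any(p < 0 | p > 1))
      errors$msgs <- c(errors$msgs,
                       "cohort.seizures.probability_any: must lie in [0, 1]")
  }
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    errors$msgs <- c(errors$msgs, "stats.alpha: must lie in (0, 1)")
  if (!cfg$qeeg$mode %in% c("terminal", "timeaverage"))
    errors$msgs <- c(errors$msgs,
                     "qeeg.mode: must be 'terminal' or 'timeaverage'")
  if (length(errors$msgs))
    stop_invalid("invalid configuration:\n  ",
                 paste(errors$msgs, collapse = "\n  "))
  cfg
}

build_cohort_spec <- function(cfg) {
  args <- cfg$cohort
  args$seed <- cfg$seed
  # YAML represents named vectors as lists; coerce them back
  num_vec <- function(x) if (is.list(x)) unlist(x) else x
  if (!is.null(args$n_per_group)) args$n_per_group <- unlist(args$n_per_group)
  if (!is.null(args$background)) {
    default_bg <- eval(formals(cohort_spec)$background)
    args$background <- utils::modifyList(default_bg,
                                         lapply(args$background, num_vec))
  }
  if (!is.null(args$seizures)) {
    sz <- args$seizures
    for (f in c("probability_any", "burden_mean_h", "burden_sd_h"))
      if (!is.null(sz[[f]])) sz[[f]] <- num_vec(sz[[f]])
    if (!is.null(sz$onset_window_h))
      sz$onset_window_h <- lapply(sz$onset_window_h, function(w)
        as.numeric(unlist(w)))
    args$seizures <- do.call(seizure_params, sz)
  }
  do.call(cohort_spec, args)
}

provenance_write_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# neoqeeg seed=%d config=%s", seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

config_hash <- function(cfg) {
  # outdir is volatile run metadata, not part of the analysis identity
  cfg$outdir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, runs preprocessing, qEEG, seizure
#' detection, VEP extraction, neuropathology scoring and the group
#' statistics, and writes per-stage CSVs, figures and a machine-readable
#' JSON summary to the output directory. Deterministic for a fixed
#' `(config, seed)`; every output embeds the seed and a config hash.
#'
#' @param config YAML path or nested list (see [validate_config()]).
#' @param seed optional override of the config seed.
#' @param outdir optional override of the output directory.
#' @param force overwrite an existing non-empty output directory.
#' @return (invisibly) the result bundle: cohort, qEEG summary, seizure
#'   profile, VEP comparison, pathology tables and the stats summary list.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, outdir = NULL,
                         force = FALSE) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (dir.exists(cfg$outdir) && length(dir(cfg$outdir)) && !force)
    stop_invalid("output directory ", cfg$outdir,
                 " is not empty (use force = TRUE)")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
  }

  spec <- stage("simulate", build_cohort_spec(cfg))
  bundle <- stage("simulate", generate_cohort(spec))
  comp <- spec$timeline_compression
  base_s <- nominal_h_to_sim_s(spec$baseline_h, comp)

  # qEEG: window auto-shrinks to the baseline span on compressed timelines
  window_s <- cfg$qeeg$window_s %||% max(4, min(30, base_s))
  qcfg_bands <- lapply(cfg$qeeg$bands, as.numeric)
  qeeg_tables <- stage("qeeg", lapply(bundle$recordings, function(rec) {
    filt <- eeg_bandpass(rec)
    qeeg_timecourse(filt, window_s = window_s,
                    overlap_fraction = cfg$qeeg$overlap_fraction,
                    bands = qcfg_bands,
                    suppressed_rms_uv = cfg$qeeg$suppressed_rms_uv,
                    edge = cfg$qeeg$edge)
  }))
  groups <- stats::setNames(bundle$animals$group, bundle$animals$animal_id)
  qeeg_summary <- stage("qeeg",
                        qeeg_group_summary(qeeg_tables, groups,
                                           mode = cfg$qeeg$mode))

  det_cfg <- do.call(detection_config, cfg$detection)
  seiz <- stage("seizure_detection", detect_cohort_seizures(bundle, det_cfg))
  profile <- stage("seizure_detection", group_onset_profile(seiz$summaries))

  vep_results <- stage("vep", cohort_vep_results(bundle))
  vep_compare <- stage("vep", group_vep_compare(vep_results,
                                                alpha = cfg$stats$alpha))

  cortical <- stage("pathology",
                    cohort_cortical_scores(bundle$pathology$fields))
  percents <- stage("pathology", percent_damaged(bundle$pathology$counts))

  alpha <- cfg$stats$alpha
  stats_summary <- stage("stats", list(
    sef = anova_groups(split(qeeg_summary$animals$sef_hz,
                             qeeg_summary$animals$group), alpha = alpha),
    entropy = anova_groups(split(qeeg_summary$animals$entropy,
                                 qeeg_summary$animals$group), alpha = alpha),
    cortical_sum = kruskal_dunn(split(cortical$sums$score_sum,
                                      cortical$sums$group),
                                p_adjust = cfg$stats$dunn_adjust,
                                alpha = alpha),
    thalamus = kruskal_dunn(
      split(percents$percent_damaged[percents$region == "thalamus"],
            percents$group[percents$region == "thalamus"]),
      p_adjust = cfg$stats$dunn_adjust, alpha = alpha)))

  wcsv <- function(df, name)
    provenance_write_csv(df, file.path(cfg$outdir, name), cfg$seed, hash)
  qeeg_long <- do.call(rbind, lapply(names(qeeg_tables), function(id)
    cbind(animal_id = id, group = groups[[id]], qeeg_tables[[id]])))
  wcsv(qeeg_long, "qeeg_timecourse.csv")
  wcsv(qeeg_summary$animals, "qeeg_animals.csv")
  wcsv(if (nrow(seiz$events)) seiz$events else
    data.frame(animal_id = character(), start_s = numeric(),
               end_s = numeric(), duration_s = numeric(),
               channel_scope = character(), dominant_hz = numeric(),
               peak_amplitude_uv = numeric()), "seizure_events.csv")
  wcsv(seiz$summaries, "seizure_summaries.csv")
  wcsv(vep_results, "vep_results.csv")
  wcsv(cortical$sums, "pathology_cortical_sums.csv")
  wcsv(percents, "pathology_percent.csv")

  test_json <- function(tr) list(
    method = tr$method, statistic = tr$statistic, df = tr$df,
    p_value = tr$p_value,
    pairwise = if (is.null(tr$pairwise)) NULL else tr$pairwise)
  summary_list <- list(
    seed = cfg$seed, config_hash = hash,
    groups = lapply(split(bundle$animals, bundle$animals$group), nrow),
    qeeg = qeeg_summary$groups,
    seizures = profile,
    vep = vep_compare$table,
    stats = lapply(stats_summary, test_json))
  jsonlite::write_json(summary_list,
                       file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  dev_ok <- capabilities("cairo")
  plot_file <- function(name)
    file.path(cfg$outdir, paste0(name, if (dev_ok) ".svg" else ".pdf"))
  save_plot <- function(p, name) {
    f <- plot_file(name)
    if (dev_ok) grDevices::svg(f, width = 7, height = 5) else
      grDevices::pdf(f, width = 7, height = 5)
    print(p)
    grDevices::dev.off()
  }
  stage("report", {
    save_plot(plot_seizure_raster(seiz, bundle$animals), "seizure_raster")
    save_plot(plot_psd_sef(bundle), "psd_sef")
  })

  invisible(list(config = cfg, bundle = bundle, qeeg = qeeg_summary,
                 seizures = seiz, seizure_profile = profile,
                 vep = vep_compare, vep_results = vep_results,
                 pathology = list(cortical = cortical, percents = percents),
                 stats = stats_summary))
}
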