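#' Region names used in the neuropathology workflow
#'
#' `cortical_regions()` are the four lobar regions scored on the 0-9
#' injury-pattern scale (each from 40 microscopy fields);
#' `subcortical_regions()` are the hippocampal and deep-gray regions
#' quantified as percent damaged neurons.
#' @return character vectors of region names.
#' @export
cortical_regions <- function() c("frontal", "parietal", "temporal", "occipital")

#' @rdname cortical_regions
#' @export
subcortical_regions <- function() c("CA1", "CA3", "caudate", "putamen",
                                    "thalamus")

#' Default pathology-simulation parameters
#'
#' Subcortical/hippocampal injury probabilities reflect the study pattern:
#' low-to-moderate injury everywhere except near-complete thalamic injury in
#' the untreated arm, strongly reduced under both treatments. Neocortical
#' field severities are drawn Dirichlet-categorical over the four-level
#' ordinal scale with group-similar base frequencies (minor injury, no
#' group effect).
#'
#' @param injury_p matrix of binomial injury probabilities,
#'   subcortical regions x groups.
#' @param neuron_total neurons counted per subcortical region.
#' @param severity_base baseline frequencies of the four severity classes.
#' @param severity_concentration Dirichlet concentration (higher = less
#'   animal-to-animal variability in field-severity profiles).
#' @param fields_per_region microscopy fields per neocortical region.
#' @return parameter list for [generate_pathology()].
#' @export
pathology_params <- function(
    injury_p = default_injury_p(),
    neuron_total = 200,
    severity_base = c(none = 0.55, scattered = 0.33,
                      `grouped/laminar` = 0.10, panlaminar = 0.02),
    severity_concentration = 30,
    fields_per_region = 40) {
  check_probability(injury_p, "injury_p")
  check_probability(severity_base, "severity_base")
  list(injury_p = injury_p, neuron_total = neuron_total,
       severity_base = severity_base / sum(severity_base),
       severity_concentration = severity_concentration,
       fields_per_region = fields_per_region)
}

default_injury_p <- function() {
  m <- matrix(0.12, nrow = length(subcortical_regions()),
              ncol = length(group_labels()),
              dimnames = list(subcortical_regions(), group_labels()))
  m["caudate", ] <- 0.15
  m["putamen", ] <- 0.15
  m["thalamus", ] <- c(0.95, 0.25, 0.25)
  m
}

#' Simulate per-animal neuropathology observations
#'
#' Subcortical/hippocampal regions: damaged neuron counts are
#' binomial(`neuron_total`, p[region, group]). Neocortical regions: per-field
#' ordinal severities (none < scattered < grouped/laminar < panlaminar) drawn
#' from an animal-specific categorical distribution sampled
#' Dirichlet(`concentration * base`).
#'
#' @param animals data frame with columns `animal_id`, `group`.
#' @param params a [pathology_params()] list.
#' @param seed integer seed (optional).
#' @return list with `counts` (animal_id, group, region, damaged, total) and
#'   `fields` (animal_id, group, region, field_index, severity).
#' @export
generate_pathology <- function(animals, params = pathology_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- list(); fields <- list()
  sev_levels <- severity_levels()
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]; grp <- animals$group[i]
    p <- params$injury_p[, grp]
    counts[[i]] <- data.frame(
      animal_id = id, group = grp, region = rownames(params$injury_p),
      damaged = stats::rbinom(length(p), params$neuron_total, p),
      total = params$neuron_total)
    fr <- lapply(cortical_regions(), function(reg) {
      probs <- rdirichlet1(params$severity_concentration *
                             params$severity_base)
      data.frame(animal_id = id, group = grp, region = reg,
                 field_index = seq_len(params$fields_per_region),
                 severity = sample(sev_levels, params$fields_per_region,
                                   replace = TRUE, prob = probs))
    })
    fields[[i]] <- do.call(rbind, fr)
  }
  list(counts = do.call(rbind, counts), fields = do.call(rbind, fields))
}
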