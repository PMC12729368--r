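#' Ordinal severity scale for neocortical injury patterns
#'
#' Four-level ordinal scale of neuronal injury extent within a microscopy
#' field: none < scattered < grouped/laminar < panlaminar.
#' @return character vector in increasing severity order.
#' @export
severity_levels <- function() {
  c("none", "scattered", "grouped/laminar", "panlaminar")
}

#' Score one neocortical region on the 0-9 injury-pattern scale
#'
#' The score is driven by the most severe injury pattern observed and by how
#' frequently it occurs across the examined fields: with worst severity
#' `s` (1 = scattered, 2 = grouped/laminar, 3 = panlaminar) present in a
#' fraction `f` of fields, the frequency tertile `t` is 1 for `f <= 1/3`,
#' 2 for `f <= 2/3`, 3 otherwise, and the score is `3 * (s - 1) + t`
#' (0 when every field is uninjured). The mapping is monotone in both the
#' worst severity and its frequency:
#'
#' | worst severity  | <= 1/3 of fields | <= 2/3 | > 2/3 |
#' |-----------------|------------------|--------|-------|
#' | none            | 0                | 0      | 0     |
#' | scattered       | 1                | 2      | 3     |
#' | grouped/laminar | 4                | 5      | 6     |
#' | panlaminar      | 7                | 8      | 9     |
#'
#' A user-supplied `score_table` (named by severity, one value per tertile)
#' can replace the default mapping.
#'
#' @param severities character vector of per-field severities (exactly
#'   `n_fields`, from [severity_levels()]).
#' @param n_fields required number of fields (default 40).
#' @param score_table optional replacement mapping: matrix
#'   `[severity 1..3, tertile 1..3]`.
#' @return integer score 0-9.
#' @export
score_region <- function(severities, n_fields = 40, score_table = NULL) {
  if (length(severities) != n_fields)
    stop_invalid("need exactly ", n_fields, " field observations, got ",
                 length(severities))
  lev <- severity_levels()
  if (!all(severities %in% lev))
    stop_invalid("unknown severity value(s): ",
                 paste(unique(setdiff(severities, lev)), collapse = ", "))
  s <- max(match(severities, lev)) - 1L      # 0..3
  if (s == 0L) return(0L)
  f <- sum(severities == lev[s + 1L]) / n_fields
  t <- if (f <= 1 / 3) 1L else if (f <= 2 / 3) 2L else 3L
  if (!is.null(score_table)) return(as.integer(score_table[s, t]))
  3L * (s - 1L) + t
}

#' Sum neocortical region scores for one animal
#'
#' @param scores named integer vector of per-region scores; all regions in
#'   `regions` must be present.
#' @param regions required region names (default the four lobar regions).
#' @return integer sum (0 to `9 * length(regions)`).
#' @export
sum_cortical_scores <- function(scores, regions = cortical_regions()) {
  missing <- setdiff(regions, names(scores))
  if (length(missing))
    stop_invalid("missing region score(s): ", paste(missing, collapse = ", "))
  sum(as.integer(scores[regions]))
}

#' Percent damaged neurons for a region
#'
#' @param counts data frame with `damaged` and `total` columns (plus any
#'   identifier columns, carried through); `total` must be positive and
#'   `0 <= damaged <= total`.
#' @return `counts` with a `percent_damaged` column (idempotent).
#' @export
percent_damaged <- function(counts) {
  if (any(counts$total <= 0))
    stop_invalid("`total` must be positive for every region")
  if (any(counts$damaged < 0 | counts$damaged > counts$total))
    stop_invalid("`damaged` must lie in [0, total]")
  counts$percent_damaged <- 100 * counts$damaged / counts$total
  counts
}

#' Score a cohort's neocortical field observations
#'
#' Applies [score_region()] per animal x region and sums per animal.
#'
#' @param fields data frame (`animal_id`, `group`, `region`, `field_index`,
#'   `severity`) as from [generate_pathology()].
#' @param n_fields fields per region (default 40).
#' @return list with `scores` (animal_id, group, region, score) and `sums`
#'   (animal_id, group, score_sum).
#' @export
cohort_cortical_scores <- function(fields, n_fields = 40) {
  key <- interaction(fields$animal_id, fields$region, drop = TRUE)
  scores <- do.call(rbind, lapply(split(fields, key), function(d)
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               region = d$region[1L],
               score = score_region(d$severity, n_fields))))
  sums <- do.call(rbind, lapply(split(scores, scores$animal_id), function(d)
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               score_sum = sum_cortical_scores(
                 stats::setNames(d$score, d$region)))))
  rownames(scores) <- rownames(sums) <- NULL
  list(scores = scores, sums = sums)
}
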