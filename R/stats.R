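# Group-level statistical layer: distributional checks, ANOVA + Tukey HSD,
# Kruskal-Wallis + Dunn, and Welch tests from summary statistics. Standard
# tests are delegated to stats/car/emmeans; Dunn's post hoc z-statistics are
# computed here from the rank-sum formulation (no installed implementation).

test_result <- function(method, statistic, df, p_value, pairwise = NULL) {
  scalar <- function(x) if (length(x) > 1L) x else unname(x)
  structure(list(method = method, statistic = scalar(statistic),
                 df = scalar(df), p_value = scalar(p_value),
                 pairwise = pairwise), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic[1L], x$p_value[1L]))
  if (!is.null(x$pairwise)) {
    cat("  pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, `3 <= n <= 5000`.
#' @return a `test_result`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop_invalid("Shapiro-Wilk needs n >= 3")
  sw <- stats::shapiro.test(values)
  test_result("Shapiro-Wilk", sw$statistic, NA_real_, sw$p.value)
}

#' Levene homogeneity-of-variances check
#'
#' Classical Levene test (deviations from the group mean by default;
#' `center = "median"` gives the Brown-Forsythe variant). Groups with zero
#' spread everywhere return a zero statistic.
#'
#' @param groups list of numeric vectors (>= 2 values each).
#' @param center `"mean"` or `"median"`.
#' @return a `test_result`.
#' @export
levene_variance <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2L) stop_invalid("need >= 2 groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  centers <- tapply(values, g, if (center == "mean") mean else stats::median)
  dev <- abs(values - centers[g])
  if (all(dev == 0))
    return(test_result("Levene", 0, c(length(groups) - 1L,
                                      length(values) - length(groups)), 1))
  lt <- car::leveneTest(values ~ g, center = if (center == "mean") mean else
    stats::median)
  test_result("Levene", lt$`F value`[1L], c(lt$Df[1L], lt$Df[2L]),
              lt$`Pr(>F)`[1L])
}

#' One- or two-way ANOVA with Tukey HSD
#'
#' One-way: `groups` is a list of numeric vectors (or `data` a data frame
#' with `value` and factor columns). Two-way (e.g. treatment x time):
#' supply `data` with two factor columns; sums of squares are Type II
#' (`car::Anova`) so unbalanced layouts are handled, and Tukey HSD contrasts
#' are computed on the marginal means of each factor (emmeans).
#'
#' @param groups list of numeric vectors for the one-way layout.
#' @param data data frame with a `value` column and factor columns named in
#'   `factors` (two-way layout).
#' @param factors character vector of 1 or 2 factor column names.
#' @param interaction include the interaction term in the two-way model.
#' @param alpha significance level for the pairwise table.
#' @return a `test_result`; `statistic`/`df`/`p_value` are vectors named by
#'   model term for the two-way layout, and `pairwise` holds Tukey-adjusted
#'   contrasts.
#' @export
anova_groups <- function(groups = NULL, data = NULL, factors = "group",
                         interaction = TRUE, alpha = 0.05) {
  if (is.null(data)) {
    if (is.null(groups) || length(groups) < 2L)
      stop_invalid("need >= 2 groups")
    data <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups) %||% seq_along(groups),
                         lengths(groups))))
    factors <- "group"
  }
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop_invalid("factor `", f, "` has fewer than 2 levels")
  }
  if (length(factors) == 1L) {
    fit <- stats::aov(stats::reformulate(factors, "value"), data = data)
    an <- summary(fit)[[1L]]
    pw <- NULL
    if (fit$df.residual >= 1) {
      tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)[[factors]]
      pw <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                       p_adj = tk[, "p adj"],
                       significant = tk[, "p adj"] < alpha)
      rownames(pw) <- NULL
    }
    return(test_result("one-way ANOVA + Tukey HSD",
                       an$`F value`[1L], c(an$Df[1L], an$Df[2L]),
                       an$`Pr(>F)`[1L], pw))
  }
  if (length(factors) != 2L) stop_invalid("1 or 2 factors supported")
  rhs <- paste(factors, collapse = if (interaction) " * " else " + ")
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = data)
  an <- car::Anova(fit, type = 2)
  terms <- setdiff(rownames(an), "Residuals")
  pw <- do.call(rbind, lapply(factors, function(f) {
    # marginal means across the other factor are intended here
    em <- suppressMessages(emmeans::emmeans(fit, f))
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    data.frame(factor = f, comparison = ct$contrast, estimate = ct$estimate,
               p_adj = ct$p.value, significant = ct$p.value < alpha)
  }))
  test_result("two-way ANOVA (Type II) + Tukey HSD",
              stats::setNames(an[terms, "F value"], terms),
              stats::setNames(an[terms, "Df"], terms),
              stats::setNames(an[terms, "Pr(>F)"], terms), pw)
}

# Dunn's z for groups i, j given pooled ranks. `tie_term` is
# sum(t^3 - t) over tie groups.
dunn_z <- function(rbar_i, rbar_j, n_i, n_j, n, tie_term) {
  se <- sqrt((n * (n + 1) / 12 - tie_term / (12 * (n - 1))) *
               (1 / n_i + 1 / n_j))
  (rbar_i - rbar_j) / se
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' H statistic (tie-corrected, via `stats::kruskal.test`) plus Dunn's
#' rank-sum post hoc z-scores computed from the pooled mean ranks with tie
#' correction. Unadjusted two-sided p-values by default (the common
#' reporting convention for Dunn's test); `p_adjust` applies a family
#' correction.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 1 value
#'   each).
#' @param p_adjust family correction passed to [stats::p.adjust()]
#'   (`"none"`, `"bonferroni"`, `"holm"`, ...).
#' @param alpha significance level for the pairwise table.
#' @return a `test_result` with the H statistic and a Dunn pairwise table.
#' @export
kruskal_dunn <- function(groups, p_adjust = "none", alpha = 0.05) {
  if (length(groups) < 2L || any(lengths(groups) < 1L))
    stop_invalid("need >= 2 groups with >= 1 value each")
  gnames <- names(groups) %||% as.character(seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(gnames, lengths(groups)), levels = gnames)
  if (stats::var(values) == 0) {
    kw_stat <- 0; kw_df <- length(groups) - 1L; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(values, g)
    kw_stat <- kw$statistic; kw_df <- kw$parameter; kw_p <- kw$p.value
  }
  r <- rank(values)
  n <- length(values)
  rbar <- tapply(r, g, mean)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  cmb <- utils::combn(gnames, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    z <- dunn_z(rbar[[a]], rbar[[b]], sum(g == a), sum(g == b), n, tie_term)
    data.frame(comparison = paste(a, "-", b), z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  pw$p_adj <- pmin(1, stats::p.adjust(pw$p, method = p_adjust))
  pw$significant <- pw$p_adj < alpha
  test_result("Kruskal-Wallis + Dunn", kw_stat, kw_df, kw_p, pw)
}

#' Welch two-sample test from summary statistics
#'
#' For comparisons where only group means, SEMs and sizes are available:
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite degrees
#' of freedom `(sem1^2 + sem2^2)^2 / (sem1^4/(n1-1) + sem2^4/(n2-1))`.
#'
#' @param mean1,sem1,n1,mean2,sem2,n2 group summaries (`sem > 0`, `n >= 2`).
#' @return a `test_result` with the t statistic, df and two-sided p.
#' @export
summary_two_sample_test <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop_invalid("need n >= 2 in both groups")
  check_positive(sem1, "sem1"); check_positive(sem2, "sem2")
  se2 <- sem1^2 + sem2^2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  p <- if (t == 0) 1 else 2 * stats::pt(-abs(t), df)
  test_result("Welch t (summary statistics)", t, df, p)
}
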