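test_that("Shapiro-Wilk calibration distinguishes normal from skewed samples", {
  keep <- reject <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    keep[s] <- shapiro_normality(rnorm(50))$p_value > 0.05
    reject[s] <- shapiro_normality(rexp(50))$p_value < 0.05
  }
  expect_gte(mean(keep), 0.9)
  expect_gte(mean(reject), 0.9)
  expect_error(shapiro_normality(c(1, 2)), "n >= 3")
})

test_that("Levene statistic is zero for spread-free groups", {
  lv <- levene_variance(list(rep(3, 5), rep(7, 5)))
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p_value, 1)
  # equal-variance samples: high p
  set.seed(40)
  lv2 <- levene_variance(list(rnorm(30), rnorm(30)))
  expect_gt(lv2$p_value, 0.05)
  expect_error(levene_variance(list(1:3)), ">= 2 groups")
})

test_that("one-way ANOVA degenerates correctly and matches the t-test identity", {
  same <- anova_groups(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(41)
  g1 <- rnorm(10); g2 <- rnorm(12, 0.5)
  a2 <- anova_groups(list(g1 = g1, g2 = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(unname(a2$statistic), unname(tt$statistic^2),
               tolerance = 1e-10)

  expect_error(anova_groups(list(a = 1:3)), ">= 2 groups")
})

test_that("ANOVA F reproduces the brute-force sums-of-squares decomposition", {
  # one-way: SS_total = SS_between + SS_within; F from the decomposition
  set.seed(42)
  groups <- list(a = rnorm(8, 0), b = rnorm(8, 1), c = rnorm(8, 0.5))
  v <- unlist(groups); g <- rep(names(groups), lengths(groups))
  grand <- mean(v)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  sst <- sum((v - grand)^2)
  expect_equal(sst, ssb + ssw, tolerance = 1e-8 * sst)
  f_oracle <- (ssb / 2) / (ssw / (length(v) - 3))
  fit <- anova_groups(groups)
  expect_equal(fit$statistic, f_oracle, tolerance = 1e-10)

  # balanced 3x2 two-way layout against the classical SS formulas
  set.seed(43)
  dat <- expand.grid(treatment = c("NT", "H2", "TH"),
                     time = c("early", "late"), rep = 1:4)
  mu <- c(NT = 0, H2 = 1, TH = 0.3)
  dat$value <- rnorm(nrow(dat)) + mu[dat$treatment] +
    ifelse(dat$time == "late", 0.5, 0)
  res <- anova_groups(data = dat, factors = c("treatment", "time"))
  grand <- mean(dat$value)
  n_ij <- 4
  ss_a <- sum(tapply(dat$value, dat$treatment, function(x)
    length(x) * (mean(x) - grand)^2))
  ss_b <- sum(tapply(dat$value, dat$time, function(x)
    length(x) * (mean(x) - grand)^2))
  cell <- tapply(dat$value, interaction(dat$treatment, dat$time), mean)
  am <- tapply(dat$value, dat$treatment, mean)
  bm <- tapply(dat$value, dat$time, mean)
  ss_ab <- 0
  for (a_ in names(am)) for (b_ in names(bm))
    ss_ab <- ss_ab + n_ij * (cell[[paste(a_, b_, sep = ".")]] -
                               am[[a_]] - bm[[b_]] + grand)^2
  ss_e <- sum((dat$value - ave(dat$value,
                               interaction(dat$treatment, dat$time)))^2)
  df_e <- nrow(dat) - 6
  expect_equal(unname(res$statistic["treatment"]),
               (ss_a / 2) / (ss_e / df_e), tolerance = 1e-10)
  expect_equal(unname(res$statistic["time"]),
               (ss_b / 1) / (ss_e / df_e), tolerance = 1e-10)
  expect_equal(unname(res$statistic["treatment:time"]),
               (ss_ab / 2) / (ss_e / df_e), tolerance = 1e-10)

  expect_error(anova_groups(data = data.frame(value = 1:4,
                                              g = rep("x", 4)),
                            factors = "g"), "fewer than 2 levels")
})

test_that("Kruskal-Wallis matches the rank-formula oracle and handles ties-free data", {
  same <- kruskal_dunn(list(a = rep(2, 3), b = rep(2, 3)))
  expect_equal(same$statistic, 0)

  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kd <- kruskal_dunn(groups)
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 with no ties
  v <- unlist(groups); r <- rank(v); n <- length(v)
  rbar <- tapply(r, rep(names(groups), lengths(groups)), mean)
  h_oracle <- 12 / (n * (n + 1)) * sum(3 * (rbar - (n + 1) / 2)^2)
  expect_equal(unname(kd$statistic), h_oracle, tolerance = 1e-12)
})

test_that("Dunn p-values agree with the exhaustive permutation null", {
  set.seed(42)
  vals <- round(rnorm(12, sd = 3) + rep(c(0, 1.5, 3), each = 4), 2)
  grp <- rep(c("a", "b", "c"), each = 4)
  obs <- kruskal_dunn(split(vals, grp))
  r <- rank(vals); n <- 12
  se <- sqrt((n * (n + 1) / 12) * (1 / 4 + 1 / 4))
  zfun <- function(ia, ib) (mean(r[ia]) - mean(r[ib])) / se
  c1 <- utils::combn(12, 4)
  count <- 0; exg <- c(0, 0, 0); exe <- c(0, 0, 0)
  obs_z <- obs$pairwise$z
  for (i in seq_len(ncol(c1))) {
    rest <- setdiff(1:12, c1[, i])
    c2 <- utils::combn(rest, 4)
    for (j in seq_len(ncol(c2))) {
      ia <- c1[, i]; ib <- c2[, j]; ic <- setdiff(rest, c2[, j])
      count <- count + 1
      zz <- c(zfun(ia, ib), zfun(ia, ic), zfun(ib, ic))
      exg <- exg + (abs(zz) > abs(obs_z) + 1e-12)
      exe <- exe + (abs(abs(zz) - abs(obs_z)) <= 1e-12)
    }
  }
  midp <- (exg + 0.5 * exe) / count   # mid-p handles the discrete null
  expect_true(all(abs(midp - obs$pairwise$p) <= 0.02))
})

test_that("family corrections only increase pairwise p-values", {
  set.seed(44)
  groups <- list(a = rnorm(6), b = rnorm(8, 1), c = rnorm(8, 2))
  raw <- kruskal_dunn(groups, p_adjust = "none")$pairwise
  bon <- kruskal_dunn(groups, p_adjust = "bonferroni")$pairwise
  expect_true(all(bon$p_adj >= raw$p_adj - 1e-12))
  expect_lte(sum(bon$significant), sum(raw$significant))

  # Tukey HSD versus unadjusted contrasts on the same fit
  dat <- data.frame(value = unlist(groups),
                    group = rep(names(groups), lengths(groups)))
  fit <- lm(value ~ group, data = dat)
  em <- emmeans::emmeans(fit, "group")
  tukey <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  none <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_true(all(tukey$p.value >= none$p.value - 1e-12))
})

test_that("summary-statistic Welch test reproduces printed and limiting cases", {
  # the reported seizure-burden comparison: 3.4 +/- 1.0 h (n = 6) vs
  # 3.1 +/- 0.7 h (n = 8) gives p ~ 0.81
  res <- summary_two_sample_test(3.4, 1.0, 6, 3.1, 0.7, 8)
  expect_equal(res$p_value, 0.81, tolerance = 0.01)

  expect_equal(summary_two_sample_test(5, 1, 6, 5, 1, 6)$p_value, 1)
  wide <- summary_two_sample_test(10, 0.5, 10, 10 + 10 * sqrt(0.5), 0.5, 10)
  expect_lt(wide$p_value, 0.001)
  expect_error(summary_two_sample_test(1, 1, 1, 2, 1, 5), "n >= 2")
  expect_error(summary_two_sample_test(1, 0, 5, 2, 1, 5), "positive")
})
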