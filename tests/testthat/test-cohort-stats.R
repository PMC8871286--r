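test_that("Spearman correlation matches hand-ranked computation", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$estimate, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3)$estimate, -1)
  # hand computation: d = (1,-1,1,-1,0), sum d^2 = 4,
  # rho = 1 - 6*4 / (5*(25-1)) = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$estimate, 0.8)
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "dixonvol_degenerate_error")
  expect_error(spearman_rho(1:2, 1:2), class = "dixonvol_sample_size_error")
})

test_that("Bland-Altman recovers hand-computed limits and symmetry", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$md, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  # d = (1, 3): MD = 2, sd = sqrt(2), limits 2 -/+ 1.96*sqrt(2)
  ba <- bland_altman(c(2, 4), c(1, 1))
  expect_equal(ba$md, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_lower, 2 - 1.96 * sqrt(2))
  expect_equal(ba$loa_upper, 2 + 1.96 * sqrt(2))
  # limits symmetric about MD; swapping the methods negates everything
  expect_equal(ba$loa_upper - ba$md, ba$md - ba$loa_lower)
  set.seed(3)
  a <- rnorm(30, 10, 3); b <- rnorm(30, 8, 3)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(r$md, -f$md)
  expect_equal(r$loa_lower, -f$loa_upper)
  expect_equal(r$loa_upper, -f$loa_lower)
  expect_error(bland_altman(1, 1), class = "dixonvol_sample_size_error")
})

test_that("summary-level limits reconstruction uses the symmetric identity", {
  lim <- bland_altman_limits(md = 2.07, loa_lower = -2.93)
  expect_equal(lim$loa_upper, 7.07)
  lim2 <- bland_altman_limits(md = 2, sd_diff = sqrt(2))
  expect_equal(lim2$loa_lower, 2 - 1.96 * sqrt(2))
  expect_error(bland_altman_limits(md = 1, loa_lower = 2),
               class = "dixonvol_domain_error")
})

test_that("ROC analysis matches exhaustive enumeration on small data", {
  r <- roc_youden(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_threshold, 2.5)
  expect_equal(r$youden_j, 1)
  # perfectly separated classes: threshold strictly between the ranges
  set.seed(4)
  neg <- runif(15, 0, 4); pos <- runif(12, 6, 10)
  rs <- roc_youden(c(neg, pos), rep(c(FALSE, TRUE), c(15, 12)))
  expect_equal(rs$auc, 1)
  expect_equal(rs$youden_j, 1)
  expect_gt(rs$youden_threshold, max(neg))
  expect_lt(rs$youden_threshold, min(pos))
  expect_error(roc_youden(1:5, rep(TRUE, 5)),
               class = "dixonvol_degenerate_label_error")
})

test_that("ROC AUC agrees with pROC and is ~0.5 for random labels", {
  set.seed(5)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5) == 1
  r <- roc_youden(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         quiet = TRUE))))
  expect_equal(r$auc, ref, tolerance = 1e-10)
  # labels independent of scores: AUC within 3 SE of 0.5
  n1 <- sum(labels); n0 <- sum(!labels)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(r$auc - 0.5), 3 * se)
})

test_that("signed-rank test reproduces exact and symmetric cases", {
  # sign-symmetric differences sit at the null centre
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p_value, 1)
  # all-positive n = 6: exact two-sided p = 2/2^6 = 0.03125 (enumeration)
  r <- wilcoxon_signed_rank(c(2, 3, 1, 4, 6, 5))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.03125)
  # zero differences are dropped and tallied
  rz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5, 6))
  expect_equal(rz$n_zero_dropped, 2)
  expect_equal(rz$n, 6)
  expect_error(wilcoxon_signed_rank(rep(0, 6)),
               class = "dixonvol_degenerate_error")
  expect_warning(wilcoxon_signed_rank(c(1, 2, 3)), "power")
})

test_that("signed-rank test detects a strong negative shift", {
  set.seed(6)
  hits <- 0
  for (i in 1:50) {
    d <- rnorm(18, mean = -1.5, sd = 1)
    if (wilcoxon_signed_rank(d)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% of replicates
})

test_that("rank-sum test reproduces exact enumeration and invariances", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation at n = 3 + 3: p = 2/C(6,3) * 1 = 0.1
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)),
               class = "dixonvol_sample_size_error")
  # rank property: invariant under strictly monotone transforms
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  p_raw <- wilcoxon_rank_sum(x, y)$p_value
  p_exp <- wilcoxon_rank_sum(exp(x), exp(y))$p_value
  expect_equal(p_raw, p_exp)
  # U / (n_a * n_b) equals the ROC AUC of the pooled scores
  r2 <- roc_youden(c(x, y), rep(c(FALSE, TRUE), c(12, 15)))
  u_y <- wilcoxon_rank_sum(y, x)$statistic
  expect_equal(r2$auc, u_y / (12 * 15))
})

test_that("repeated-measures ANOVA recovers a known decomposition", {
  grid <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:20),
                             timepoint = c("baseline", "week8"))
  grid$arm <- ifelse(grid$subject_id %in% sprintf("s%02d", 1:10),
                     "mufa", "multifactorial")
  # pure arm offset, no time effect or interaction
  set.seed(8)
  subj_noise <- rnorm(20, 0, 0.5)
  names(subj_noise) <- sprintf("s%02d", 1:20)
  grid$value <- ifelse(grid$arm == "mufa", 0, 10) +
    subj_noise[grid$subject_id] + rnorm(nrow(grid), 0, 0.3)
  res <- rm_anova_two_way(grid, value)
  expect_equal(res$effect, c("arm", "time", "arm:time"))
  expect_lt(res$p_value[res$effect == "arm"], 1e-6)
  expect_gt(res$p_value[res$effect == "arm:time"], 0.05)
  # independent oracle: explicit sums-of-squares decomposition
  wide <- tidyr::pivot_wider(grid, names_from = timepoint,
                             values_from = value)
  subj_mean <- (wide$baseline + wide$week8) / 2
  arm_f <- wide$arm
  grand <- mean(subj_mean)
  ss_arm <- 2 * sum(tapply(subj_mean, arm_f, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_subj_within <- 2 * sum((subj_mean - ave(subj_mean, arm_f))^2)
  f_arm <- (ss_arm / 1) / (ss_subj_within / 18)
  expect_equal(res$statistic[res$effect == "arm"], f_arm, tolerance = 1e-8)
})

test_that("ANOVA flags degenerate and incomplete designs", {
  grid <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                             timepoint = c("baseline", "week8"))
  grid$arm <- rep(c("a", "b"), each = 6)
  grid$value <- 1
  expect_error(rm_anova_two_way(grid, value),
               class = "dixonvol_degenerate_error")
  grid$value <- rnorm(12)
  expect_error(rm_anova_two_way(grid[-1, ], value),
               class = "dixonvol_design_error")
})

test_that("an injected interaction is detected with high power", {
  # interaction only in arm 2's week-8 values, effect/noise ratio 2
  set.seed(9)
  hits <- 0
  n_rep <- 30
  for (rep in 1:n_rep) {
    grid <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:36),
                               timepoint = c("baseline", "week8"))
    grid$arm <- ifelse(grid$subject_id %in% sprintf("s%02d", 1:18),
                       "mufa", "multifactorial")
    eff <- ifelse(grid$arm == "multifactorial" & grid$timepoint == "week8",
                  -2, 0)
    grid$value <- 10 + eff + rnorm(nrow(grid), 0, 1)
    p <- rm_anova_two_way(grid, value)
    if (p$p_value[p$effect == "arm:time"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
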