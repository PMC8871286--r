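#' Spearman rank correlation
#'
#' Spearman's rho as the Pearson correlation of mid-ranks (average ranks
#' on ties), with a two-sided p-value from the t approximation. Thin
#' wrapper over [stats::cor.test()] returning a broom-style one-row
#' tibble.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return One-row tibble: `estimate` (rho), `statistic` (S), `p_value`,
#'   `n`, `method`.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "dixonvol_sample_size_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Missing values are not allowed.", class = "dixonvol_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for a constant vector.",
          class = "dixonvol_degenerate_error")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = length(x),
         method = "Spearman rank correlation (t approximation)")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` between two paired measurement methods:
#' mean difference (MD, the systematic bias of method A over method B),
#' sample SD of the differences, and the 95% limits of agreement
#' `MD +/- 1.96 * SD`, which are symmetric about MD by construction.
#'
#' @param a,b Paired numeric vectors (method A, method B), length >= 2.
#' @return Object of class `bland_altman` with fields `md`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`, and the per-pair `data` tibble
#'   (means and differences) used for plotting.
#' @examples
#' ba <- bland_altman(c(2, 4), c(1, 1))
#' ba$md       # 2
#' ba$sd_diff  # sqrt(2)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must be paired (equal length).",
          class = "dixonvol_sample_size_error")
  }
  if (length(a) < 2) {
    abort("Bland-Altman needs at least 2 pairs.",
          class = "dixonvol_sample_size_error")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("Missing values are not allowed.", class = "dixonvol_domain_error")
  }
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  structure(list(
    md = md, sd_diff = s,
    loa_lower = md - 1.96 * s, loa_upper = md + 1.96 * s,
    n = length(d),
    data = tibble(mean = (a + b) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, MD = %.3f, 95%% limits of agreement [%.3f, %.3f]\n",
    x$n, x$md, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Reconstruct Bland-Altman limits from summary values
#'
#' The limits of agreement are symmetric about the mean difference, so
#' any two of (MD, SD of differences, lower limit) determine the rest:
#' `loa_upper = 2 * md - loa_lower = md + 1.96 * sd_diff`.
#'
#' @param md Mean difference.
#' @param loa_lower Lower limit of agreement (supply this or `sd_diff`).
#' @param sd_diff SD of the paired differences.
#' @return One-row tibble: `md`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @examples
#' bland_altman_limits(md = 2.07, loa_lower = -2.93)$loa_upper  # 7.07
#' @export
bland_altman_limits <- function(md, loa_lower = NULL, sd_diff = NULL) {
  if (is.null(loa_lower) && is.null(sd_diff)) {
    abort("Supply `loa_lower` or `sd_diff`.", class = "dixonvol_config_error")
  }
  if (is.null(sd_diff)) sd_diff <- (md - loa_lower) / 1.96
  if (sd_diff < 0) {
    abort("`loa_lower` must not exceed `md`.", class = "dixonvol_domain_error")
  }
  tibble(md = md, sd_diff = sd_diff,
         loa_lower = md - 1.96 * sd_diff, loa_upper = md + 1.96 * sd_diff)
}

#' ROC analysis with Youden-index threshold selection
#'
#' Empirical ROC of a continuous score against binary labels. Candidate
#' thresholds are the midpoints between adjacent distinct sorted scores
#' plus infinite sentinels; a case is called positive when
#' `score > threshold`. The AUC is the trapezoidal area under the
#' empirical curve (identical to the normalised Mann-Whitney U
#' statistic), and the selected threshold maximises Youden's
#' J = sensitivity + specificity - 1, ties broken toward the lowest
#' threshold.
#'
#' @param scores Numeric scores (e.g. MRI-PDFF values).
#' @param labels Logical (or 0/1) reference labels; both classes must be
#'   present.
#' @return Object of class `roc_youden`: `auc`, `youden_threshold`,
#'   `youden_j`, `n_pos`, `n_neg`, and `operating_points` (tibble of
#'   threshold, sensitivity, specificity, j).
#' @examples
#' r <- roc_youden(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc               # 1
#' r$youden_threshold  # 2.5
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must be complete and of equal length.",
          class = "dixonvol_domain_error")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present in `labels`.",
          class = "dixonvol_degenerate_label_error")
  }
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  op <- purrr::map_dfr(thr, function(t) {
    tibble(threshold = t,
           sensitivity = mean(scores[labels] > t),
           specificity = mean(scores[!labels] <= t))
  })
  op$j <- op$sensitivity + op$specificity - 1
  # AUC via mid-ranks: U / (n_pos * n_neg), equal to the trapezoid area
  r <- rank(scores)
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  best <- which(op$j == max(op$j))[1]  # lowest threshold on ties
  structure(list(
    auc = auc,
    youden_threshold = op$threshold[best],
    youden_j = op$j[best],
    n_pos = n_pos, n_neg = n_neg,
    operating_points = op
  ), class = "roc_youden")
}

#' @export
print.roc_youden <- function(x, ...) {
  cat(sprintf(
    "<roc_youden> AUC = %.3f (n+ = %d, n- = %d); Youden threshold = %.4g (J = %.3f)\n",
    x$auc, x$n_pos, x$n_neg, x$youden_threshold, x$youden_j))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (tallied in `n_zero_dropped`); ranks are mid-ranks on ties.
#' The exact null distribution is used for n <= 25 without ties,
#' otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param x Differences, or first member of each pair if `y` is given.
#' @param y Optional second member; differences are `x - y`.
#' @return One-row tibble: `statistic` (V), `p_value`, `n` (non-zero
#'   pairs), `n_zero_dropped`, `exact`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 1, 4, 6, 5))$p_value  # exact, 0.03125
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) {
    abort("Missing values are not allowed.", class = "dixonvol_domain_error")
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("All paired differences are zero.",
          class = "dixonvol_degenerate_error")
  }
  if (n < 5) {
    warn("Fewer than 5 non-zero differences; the test has little power.")
  }
  has_ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !has_ties
  ht <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
         n = n, n_zero_dropped = n_zero, exact = exact,
         method = "Wilcoxon signed-rank (two-sided)")
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' Two-sided comparison of two independent groups, used to compare
#' changes and percent changes between dietary arms. Exact enumeration
#' when the combined sample is <= 20 without ties; otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic` (U for the first group),
#'   `p_value`, `n_x`, `n_y`, `exact`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "dixonvol_sample_size_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Missing values are not allowed.", class = "dixonvol_domain_error")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !has_ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
         n_x = length(x), n_y = length(y), exact = exact,
         method = "Wilcoxon rank-sum (two-sided)")
}

#' Two-way repeated-measures ANOVA (diet x time)
#'
#' Standard mixed two-way decomposition for a between-subject factor
#' (dietary arm) crossed with a within-subject factor (timepoint): the
#' arm effect is tested against the between-subject error stratum, the
#' time and arm-by-time effects against the subject-by-time residual.
#' Requires a complete balanced-within design (every subject measured at
#' both timepoints).
#'
#' @param data Long tibble with one value per subject-timepoint.
#' @param value Value column (tidy-eval).
#' @param subject,arm,time Design columns (tidy-eval); default to
#'   `subject_id`, `arm`, `timepoint`.
#' @return Tibble with one row per effect (`arm`, `time`, `arm:time`):
#'   `df`, `df_error`, `statistic` (F), `p_value`.
#' @export
rm_anova_two_way <- function(data, value, subject = subject_id,
                             arm = arm, time = timepoint) {
  stopifnot(is.data.frame(data))
  df <- dplyr::transmute(
    data,
    v = {{ value }},
    s = factor({{ subject }}),
    a = factor({{ arm }}),
    t = factor({{ time }})
  )
  if (anyNA(df)) {
    abort("Missing values are not allowed.", class = "dixonvol_domain_error")
  }
  counts <- table(df$s)
  n_time <- length(levels(df$t))
  if (n_time < 2 || any(counts != n_time)) {
    bad <- names(counts)[counts != n_time]
    abort(paste0("Incomplete design: subject(s) without all timepoints: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "dixonvol_design_error")
  }
  if (var(df$v) == 0) {
    abort("Values have zero variance; F statistics undefined.",
          class = "dixonvol_degenerate_error")
  }
  fit <- aov(v ~ a * t + Error(s), data = df)
  sm <- summary(fit)
  tab_b <- as.data.frame(sm[["Error: s"]][[1]])
  tab_w <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(tab_b))
  rn_w <- trimws(rownames(tab_w))
  pick <- function(tab, rn, eff) {
    i <- which(rn == eff)
    c(df = unname(tab$Df[i]), f = unname(tab$`F value`[i]),
      p = unname(tab$`Pr(>F)`[i]))
  }
  b <- pick(tab_b, rn_b, "a")
  tw <- pick(tab_w, rn_w, "t")
  it <- pick(tab_w, rn_w, "a:t")
  tibble(
    effect = c("arm", "time", "arm:time"),
    df = unname(c(b["df"], tw["df"], it["df"])),
    df_error = c(tab_b$Df[rn_b == "Residuals"],
                 rep(tab_w$Df[rn_w == "Residuals"], 2)),
    statistic = unname(c(b["f"], tw["f"], it["f"])),
    p_value = unname(c(b["p"], tw["p"], it["p"]))
  )
}
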