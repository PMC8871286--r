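#' Tidy a Bland-Altman result
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return One-row tibble: `md`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(md = x$md, sd_diff = x$sd_diff,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n)
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

#' Tidy a ROC/Youden result
#'
#' `tidy()` returns the operating points (one row per candidate
#' threshold); `glance()` the one-row model summary.
#'
#' @param x A `roc_youden` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.roc_youden <- function(x, ...) x$operating_points

#' @rdname tidy.roc_youden
#' @export
glance.roc_youden <- function(x, ...) {
  tibble(auc = x$auc, youden_threshold = x$youden_threshold,
         youden_j = x$youden_j, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a study's analysis
#'
#' `tidy()` stacks every hypothesis test of the analysis into one long
#' tibble; `glance()` gives the one-row headline summary (correlation,
#' agreement and ROC numbers).
#'
#' @param x A `dixon_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dixon_study <- function(x, ...) {
  a <- x$analysis
  dplyr::bind_rows(
    dplyr::transmute(a$paired_tests,
                     test = "paired_signed_rank", measure = .data$measure,
                     group = .data$arm, statistic = .data$statistic,
                     p_value = .data$p_value),
    if (!is.null(a$change_tests))
      dplyr::transmute(a$change_tests,
                       test = "rank_sum", measure = .data$measure,
                       group = .data$quantity, statistic = .data$statistic,
                       p_value = .data$p_value),
    dplyr::transmute(a$anova,
                     test = "rm_anova", measure = .data$measure,
                     group = .data$effect, statistic = .data$statistic,
                     p_value = .data$p_value)
  )
}

#' @rdname tidy.dixon_study
#' @export
glance.dixon_study <- function(x, ...) {
  a <- x$analysis
  rho_voi <- a$correlations$estimate[a$correlations$comparison == "voi_vs_mrs"]
  rho_wl <- a$correlations$estimate[a$correlations$comparison == "wl_vs_mrs"]
  md_voi <- a$agreement$md[a$agreement$comparison == "voi_vs_mrs"]
  tibble(
    n_subjects = sum(x$config$n_per_arm),
    rho_voi_mrs = rho_voi %||% NA_real_,
    rho_wl_mrs = rho_wl %||% NA_real_,
    md_voi_mrs = md_voi %||% NA_real_,
    auc_voi = if (!is.null(a$roc$voi)) a$roc$voi$auc else NA_real_,
    auc_wl = if (!is.null(a$roc$wl)) a$roc$wl$auc else NA_real_,
    youden_voi = if (!is.null(a$roc$voi)) a$roc$voi$youden_threshold
                 else NA_real_,
    youden_wl = if (!is.null(a$roc$wl)) a$roc$wl$youden_threshold
                else NA_real_
  )
}
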