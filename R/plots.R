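#' Bland-Altman plot
#'
#' Pairwise means against differences, with the mean difference and the
#' 95% limits of agreement as horizontal lines.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$md, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of methods (PDFF %)",
                  y = "Difference (PDFF %-points)",
                  title = sprintf("Bland-Altman: MD %.2f, LoA [%.2f, %.2f]",
                                  object$md, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' ROC curve with the Youden-optimal operating point
#'
#' @param object A `roc_youden` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_youden <- function(object, ...) {
  op <- object$operating_points
  best <- op[op$threshold == object$youden_threshold, ][1, ]
  ggplot2::ggplot(op, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = best, colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC: AUC %.3f, Youden threshold %.3g%%",
                                  object$auc, object$youden_threshold)) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-subject changes by arm
#'
#' @param changes Changes tibble (see [paired_changes()] /
#'   `analyze_cohort()$changes`), with `arm`, `measure` and the chosen
#'   quantity column.
#' @param quantity `"change"` (absolute, %-points) or `"percent_change"`.
#' @return A ggplot.
#' @export
plot_lv_changes <- function(changes, quantity = c("change", "percent_change")) {
  quantity <- match.arg(quantity)
  stopifnot(is.data.frame(changes), "arm" %in% names(changes))
  ggplot2::ggplot(changes,
                  ggplot2::aes(x = .data$arm, y = .data[[quantity]],
                               fill = .data$arm)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 21) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = if (quantity == "change") "Change (%-points)"
                      else "Percent change (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
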