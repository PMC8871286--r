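#' Percentage of liver volume above a steatosis threshold (LV%)
#'
#' The volumetric steatosis statistic: the percentage of liver-mask voxels
#' whose PDFF exceeds the threshold `th`. "Above" is strict (`>`) by
#' default, so voxels exactly at the threshold are not counted as
#' steatotic; set `ge = TRUE` for a `>=` sensitivity analysis. The
#' conventional cutoff separating normal liver from fatty liver is
#' 5.56%.
#'
#' @param map A [pdff_map()].
#' @param th Threshold(s) in percent, each in [0, 100]. May be a vector.
#' @param ge Use `>=` instead of strict `>`. Default `FALSE`.
#' @return Numeric vector of LV% values (percent of masked voxels), one
#'   per threshold, named by threshold.
#' @examples
#' m <- pdff_map(vol_grid(array(10, c(8, 8, 8))),
#'               vol_grid(array(1, c(8, 8, 8))))
#' lv_percent_above(m, c(5.56, 10))  # 100 then 0 (strict)
#' @export
lv_percent_above <- function(map, th, ge = FALSE) {
  stopifnot(inherits(map, "pdff_map"))
  if (any(!is.finite(th)) || any(th < 0 | th > 100)) {
    abort("Thresholds must lie in [0, 100] percent.",
          class = "dixonvol_domain_error")
  }
  vals <- map$map$values[map$mask$values == 1]
  n <- length(vals)
  if (n == 0) {
    abort("Liver mask is empty.", class = "dixonvol_region_error")
  }
  out <- vapply(th, function(t) {
    100 * (if (ge) sum(vals >= t) else sum(vals > t)) / n
  }, numeric(1))
  names(out) <- format(th, trim = TRUE)
  out
}

#' Liver volume of a mask in millilitres
#'
#' @param mask Binary `vol_grid`.
#' @return Volume in mL (voxel count times voxel volume).
#' @export
liver_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "vol_grid"))
  sum(mask$values) * prod(mask$voxel_size) / 1000
}

#' Paired baseline / 8-week changes for one measure
#'
#' Computes, per subject, `change = week8 - baseline` and
#' `percent_change = 100 * change / baseline` for a measure held in a
#' cohort results table. Subjects with a zero baseline keep their absolute
#' change but get `NA` percent change (flagged via
#' `percent_change_defined`); callers exclude them from percent-change
#' statistics.
#'
#' @param data Cohort results tibble with columns `subject_id`,
#'   `timepoint` (values `"baseline"` and `"week8"`), optionally `arm`,
#'   and the measure column.
#' @param measure Measure column (tidy-eval).
#' @return Tibble with one row per subject: `subject_id`, `arm` (if
#'   present), `measure`, `baseline`, `week8`, `change`, `percent_change`,
#'   `percent_change_defined`.
#' @examples
#' tb <- tibble::tibble(
#'   subject_id = c("s1", "s1"), timepoint = c("baseline", "week8"),
#'   lv_5.56 = c(73.64, 56.03))
#' paired_changes(tb, lv_5.56)$change  # -17.61
#' @export
paired_changes <- function(data, measure) {
  stopifnot(is.data.frame(data))
  measure <- rlang::enquo(measure)
  name <- rlang::as_name(measure)
  if (!all(c("subject_id", "timepoint") %in% names(data))) {
    abort("`data` needs `subject_id` and `timepoint` columns.",
          class = "dixonvol_pairing_error")
  }
  bad <- setdiff(unique(data$timepoint), c("baseline", "week8"))
  if (length(bad)) {
    abort(paste0("Unknown timepoint(s): ", paste(bad, collapse = ", ")),
          class = "dixonvol_pairing_error")
  }
  has_arm <- "arm" %in% names(data)
  keys <- if (has_arm) c("subject_id", "arm") else "subject_id"
  wide <- data |>
    dplyr::select(dplyr::all_of(c(keys, "timepoint")), value = !!measure) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  if (!all(c("baseline", "week8") %in% names(wide)) ||
      anyNA(wide$baseline) || anyNA(wide$week8)) {
    missing_subj <- wide$subject_id[
      !stats::complete.cases(wide[c("baseline", "week8")])]
    if (!length(missing_subj)) missing_subj <- unique(data$subject_id)
    abort(paste0("Subject(s) missing a timepoint for `", name, "`: ",
                 paste(utils::head(missing_subj, 5), collapse = ", ")),
          class = "dixonvol_pairing_error")
  }
  wide |>
    dplyr::mutate(
      measure = name,
      change = .data$week8 - .data$baseline,
      percent_change_defined = .data$baseline != 0,
      percent_change = dplyr::if_else(.data$percent_change_defined,
                                      100 * .data$change / .data$baseline,
                                      NA_real_)
    ) |>
    dplyr::relocate("measure", .after = dplyr::all_of(keys))
}

#' Label steatosis from a PDFF value
#'
#' Strict threshold rule: steatotic iff `pdff > cutoff`. The default
#' cutoff is the conventional 5.56% separating normal from fatty liver.
#'
#' @param pdff PDFF value(s) in percent, each in [0, 100].
#' @param cutoff Cutoff in percent. Default 5.56.
#' @return Logical vector.
#' @export
steatosis_label <- function(pdff, cutoff = 5.56) {
  if (any(!is.finite(pdff)) || any(pdff < 0 | pdff > 100)) {
    abort("PDFF values must lie in [0, 100] percent.",
          class = "dixonvol_domain_error")
  }
  pdff > cutoff
}
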