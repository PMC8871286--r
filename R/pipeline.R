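#' Quantify one subject-timepoint's images
#'
#' Runs the mapping chain on a set of Dixon images: optional two-point
#' separation, fat-fraction mapping, VOI placement, and extraction of the
#' whole-liver mean, VOI mean and LV% values.
#'
#' @param images Named list with `water`/`fat` (and, for the
#'   in-phase/opposed-phase dialect, `in_phase`/`opposed_phase`)
#'   `vol_grid`s.
#' @param mask Binary liver mask `vol_grid`.
#' @param voi A [voi_spec()].
#' @param thresholds LV% thresholds (%).
#' @param dialect `"water_fat"` (scanner-provided water/fat images,
#'   default) or `"ip_op"` (recompute water/fat from in-phase and
#'   opposed-phase).
#' @return One-row tibble: `mri_pdff_voi`, `mri_pdff_wl`, `lv_<th>`
#'   columns and `liver_volume_ml`.
#' @export
quantify_images <- function(images, mask, voi,
                            thresholds = c(5.56, 7.97, 8.8),
                            dialect = c("water_fat", "ip_op")) {
  dialect <- match.arg(dialect)
  if (dialect == "ip_op") {
    wf <- separate_two_point(images$in_phase, images$opposed_phase)
  } else {
    wf <- images[c("water", "fat")]
  }
  map <- fat_fraction_map(wf$water, wf$fat, mask)
  voi_mask <- place_voi(map, voi)
  lv <- lv_percent_above(map, thresholds)
  out <- tibble(
    mri_pdff_voi = mean_pdff(map, voi_mask),
    mri_pdff_wl = mean_pdff(map),
    liver_volume_ml = liver_volume_ml(mask)
  )
  for (i in seq_along(thresholds)) {
    out[[lv_col(thresholds[i])]] <- lv[[i]]
  }
  out
}

lv_col <- function(th) paste0("lv_", format(th, trim = TRUE))

#' Quantify a simulated cohort into a results table
#'
#' Applies MRS quantification and the full image chain to every
#' subject-timepoint of a simulated cohort, yielding the long cohort
#' results table all statistics consume.
#'
#' @param cohort A `dixon_cohort` from [simulate_cohort()] with volumes
#'   kept.
#' @param thresholds LV% thresholds (%); defaults to the generator
#'   config's.
#' @param dialect Input dialect, see [quantify_images()].
#' @return Tibble with one row per subject-timepoint: `subject_id`,
#'   `arm`, `timepoint`, `mrs_pdff`, `mri_pdff_voi`, `mri_pdff_wl`,
#'   `lv_<th>` columns and `liver_volume_ml`.
#' @export
quantify_cohort <- function(cohort, thresholds = NULL,
                            dialect = c("water_fat", "ip_op")) {
  stopifnot(inherits(cohort, "dixon_cohort"))
  dialect <- match.arg(dialect)
  cfg <- attr(cohort, "config")
  thresholds <- thresholds %||% cfg$thresholds
  unwrap_stage_errors(purrr::pmap_dfr(
    list(cohort$subject_id, cohort$arm, cohort$timepoint, cohort$truth,
         cohort$images, cohort$mrs, cohort$voi),
    function(sid, arm, tp, truth, images, mrs, voi) {
      if (is.null(images)) {
        abort("Cohort was simulated with `keep_volumes = FALSE`.",
              class = "dixonvol_config_error")
      }
      q <- with_stage("map", sid,
                      quantify_images(images, truth$mask, voi, thresholds,
                                      dialect))
      dplyr::bind_cols(
        tibble(subject_id = sid, arm = arm, timepoint = tp,
               mrs_pdff = with_stage("mrs", sid, mrs_pdff(mrs))),
        q)
    }))
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s, subject %s] %s", stage, subject_id,
                  conditionMessage(e)),
          class = "dixonvol_stage_error", parent = e)
  })
}

# purrr wraps callback errors in an indexed condition; re-signal the
# stage-tagged error so callers see the stage and subject directly.
unwrap_stage_errors <- function(expr) {
  tryCatch(expr, error = function(e) {
    p <- e
    while (!is.null(p)) {
      if (inherits(p, "dixonvol_stage_error")) rlang::cnd_signal(p)
      p <- p$parent
    }
    stop(e)
  })
}

#' Arm-by-timepoint summary of a cohort results table
#'
#' Mean and sample SD per arm, timepoint and measure ("mean +/- SD"
#' reporting). SD is `NA` for a single subject.
#'
#' @param data Cohort results tibble (see [quantify_cohort()]).
#' @return Long tibble: `arm`, `timepoint`, `measure`, `n`, `mean`, `sd`.
#' @export
summarize_cohort <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  meas <- measure_columns(data)
  data |>
    tidyr::pivot_longer(dplyr::all_of(meas), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$arm, .data$timepoint, .data$measure) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
}

measure_columns <- function(data) {
  cand <- c("mrs_pdff", "mri_pdff_voi", "mri_pdff_wl",
            grep("^lv_", names(data), value = TRUE))
  intersect(cand, names(data))
}

#' Full statistical analysis of a cohort results table
#'
#' Reproduces the study's statistical layer on a results table:
#' Spearman correlations and Bland-Altman agreement between the three
#' PDFF measurements (pooled over arms and timepoints), per-arm paired
#' signed-rank tests, two-way repeated-measures ANOVA per measure,
#' paired changes and percent changes with between-arm rank-sum tests,
#' and ROC/Youden derivation of MRI-PDFF steatosis cutoffs against
#' MRS-based labels.
#'
#' @param results Cohort results tibble (see [quantify_cohort()]).
#' @param steatosis_cutoff MRS-PDFF cutoff (%) defining the steatosis
#'   label for the ROC analysis. Default 5.56.
#' @return Object of class `dixon_analysis`: tibbles `correlations`,
#'   `agreement`, `paired_tests`, `anova`, `changes`, `change_tests`;
#'   list `bland_altman` (fitted objects) and `roc` (`voi`, `wl`).
#' @export
analyze_cohort <- function(results, steatosis_cutoff = 5.56) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  meas <- measure_columns(results)
  pairs <- list(voi_vs_mrs = c("mri_pdff_voi", "mrs_pdff"),
                wl_vs_mrs = c("mri_pdff_wl", "mrs_pdff"),
                voi_vs_wl = c("mri_pdff_voi", "mri_pdff_wl"))
  pairs <- purrr::keep(pairs, ~ all(.x %in% meas))

  correlations <- purrr::imap_dfr(pairs, function(p, nm) {
    dplyr::mutate(spearman_rho(results[[p[1]]], results[[p[2]]]),
                  comparison = nm, .before = 1)
  })
  ba <- purrr::map(pairs, ~ bland_altman(results[[.x[1]]], results[[.x[2]]]))
  agreement <- purrr::imap_dfr(ba, function(b, nm) {
    tibble(comparison = nm, n = b$n, md = b$md, sd_diff = b$sd_diff,
           loa_lower = b$loa_lower, loa_upper = b$loa_upper)
  })

  changes <- purrr::map_dfr(meas, function(m) {
    paired_changes(results, !!rlang::sym(m))
  })

  # degenerate inputs (all-zero changes, too-few defined percent changes)
  # yield an NA row rather than aborting the whole analysis
  safe_test <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      tibble(statistic = NA_real_, p_value = NA_real_,
             method = paste0("not computed: ", conditionMessage(e)))
    })
  }

  arms <- sort(unique(results$arm))
  paired_tests <- purrr::map_dfr(meas, function(m) {
    purrr::map_dfr(arms, function(a) {
      ch <- changes[changes$measure == m & changes$arm == a, ]
      dplyr::mutate(safe_test(wilcoxon_signed_rank(ch$change)),
                    measure = m, arm = a, .before = 1)
    })
  })

  change_tests <- NULL
  if (length(arms) == 2) {
    change_tests <- purrr::map_dfr(meas, function(m) {
      ch <- changes[changes$measure == m, ]
      g <- split(ch, ch$arm)
      abs_t <- dplyr::mutate(
        safe_test(wilcoxon_rank_sum(g[[arms[1]]]$change,
                                    g[[arms[2]]]$change)),
        measure = m, quantity = "change", .before = 1)
      pc1 <- g[[arms[1]]]$percent_change
      pc2 <- g[[arms[2]]]$percent_change
      pct_t <- dplyr::mutate(
        safe_test(wilcoxon_rank_sum(pc1[!is.na(pc1)], pc2[!is.na(pc2)])),
        measure = m, quantity = "percent_change", .before = 1)
      dplyr::bind_rows(abs_t, pct_t)
    })
  }

  anova_tab <- purrr::map_dfr(meas, function(m) {
    dplyr::mutate(rm_anova_two_way(results, !!rlang::sym(m)),
                  measure = m, .before = 1)
  })

  roc <- list(voi = NULL, wl = NULL)
  if ("mrs_pdff" %in% meas) {
    labels <- steatosis_label(results$mrs_pdff, steatosis_cutoff)
    safe_roc <- function(scores) {
      tryCatch(roc_youden(scores, labels), error = function(e) NULL)
    }
    if ("mri_pdff_voi" %in% meas) roc$voi <- safe_roc(results$mri_pdff_voi)
    if ("mri_pdff_wl" %in% meas) roc$wl <- safe_roc(results$mri_pdff_wl)
  }

  structure(list(
    correlations = correlations, agreement = agreement,
    bland_altman = ba, paired_tests = paired_tests,
    anova = anova_tab, changes = changes, change_tests = change_tests,
    roc = roc, steatosis_cutoff = steatosis_cutoff
  ), class = "dixon_analysis")
}

#' @export
print.dixon_analysis <- function(x, ...) {
  cat("<dixon_analysis>\n")
  cat("Correlations (Spearman):\n")
  print(as.data.frame(x$correlations[c("comparison", "estimate", "p_value")]),
        row.names = FALSE)
  cat("Bland-Altman agreement:\n")
  print(as.data.frame(x$agreement), row.names = FALSE)
  if (!is.null(x$roc$voi)) {
    cat(sprintf("ROC (VOI scores): AUC %.3f, Youden threshold %.3f%%\n",
                x$roc$voi$auc, x$roc$voi$youden_threshold))
  }
  if (!is.null(x$roc$wl)) {
    cat(sprintf("ROC (WL scores):  AUC %.3f, Youden threshold %.3f%%\n",
                x$roc$wl$auc, x$roc$wl$youden_threshold))
  }
  invisible(x)
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort, quantifies every subject through the MRS and
#' imaging chains, and runs the complete statistical analysis. Subjects
#' are processed in a stream (volumes are dropped after quantification)
#' so large cohorts fit in memory. Deterministic for a given config.
#'
#' @param config A [generator_config()].
#' @param dialect Input dialect for the mapping stage, see
#'   [quantify_images()].
#' @param out_dir Optional output directory; when given, writes the
#'   results/changes/summary CSVs, a stats JSON, the config and a
#'   provenance record (and figures, where a graphics device is
#'   available).
#' @return Object of class `dixon_study`: `config`, `results` (cohort
#'   results tibble), `summary`, `analysis` (a `dixon_analysis`),
#'   `provenance`.
#' @examples
#' \donttest{
#' cfg <- generator_config(n_per_arm = 3, grid_shape = c(12, 12, 8),
#'                         voxel_size = c(3, 3, 3), voi_side = 9, seed = 2)
#' st <- run_study(cfg)
#' st$summary
#' }
#' @export
run_study <- function(config, dialect = c("water_fat", "ip_op"),
                      out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  dialect <- match.arg(dialect)
  effects <- with_stage("simulate", "-", draw_subject_effects(config))
  results <- unwrap_stage_errors(purrr::pmap_dfr(
    list(effects$subject_id, effects$arm, seq_len(nrow(effects)),
         effects$baseline, effects$change),
    function(sid, arm, idx, b, c_) {
      sub <- with_stage("simulate", sid,
                        simulate_subject(sid, arm, idx, b, c_, config,
                                         keep_volumes = TRUE))
      purrr::pmap_dfr(
        list(sub$timepoint, sub$truth, sub$images, sub$mrs, sub$voi),
        function(tp, truth, images, mrs, voi) {
          q <- with_stage("map", sid,
                          quantify_images(images, truth$mask, voi,
                                          config$thresholds, dialect))
          dplyr::bind_cols(
            tibble(subject_id = sid, arm = arm, timepoint = tp,
                   mrs_pdff = with_stage("mrs", sid, mrs_pdff(mrs)),
                   true_mean_pdff = sub$true_mean_pdff[sub$timepoint == tp],
                   target_effect = sub$target_effect[sub$timepoint == tp]),
            q)
        })
    }))
  n_total <- sum(config$n_per_arm)
  if (n_total < 10) {
    warn(sprintf("Small cohort (%d subjects): statistics are fragile.",
                 n_total))
  }
  analysis <- with_stage("stats", "-", analyze_cohort(results))
  study <- structure(list(
    config = config,
    results = results,
    summary = summarize_cohort(results),
    analysis = analysis,
    provenance = list(
      package = "dixonvol",
      version = as.character(utils::packageVersion("dixonvol")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config))
    )
  ), class = "dixon_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.dixon_study <- function(x, ...) {
  cat(sprintf("<dixon_study> %d subjects (%d MUFA / %d multifactorial), seed %d\n",
              sum(x$config$n_per_arm), x$config$n_per_arm[["mufa"]],
              x$config$n_per_arm[["multifactorial"]], x$config$seed))
  print(x$analysis)
  invisible(x)
}

#' Write a study's tables, stats and provenance to disk
#'
#' CSV tables are rounded to two decimals; full-precision values go to
#' the JSON sidecars.
#'
#' @param study A `dixon_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dixon_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round2 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, 2)))
  }
  utils::write.csv(round2(study$results), file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(round2(study$analysis$changes),
                   file.path(dir, "changes.csv"), row.names = FALSE)
  utils::write.csv(round2(study$summary), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  a <- study$analysis
  stats <- list(
    correlations = a$correlations, agreement = a$agreement,
    paired_tests = a$paired_tests, anova = a$anova,
    change_tests = a$change_tests,
    roc = purrr::map(purrr::compact(a$roc), function(r) {
      list(auc = r$auc, youden_threshold = r$youden_threshold,
           youden_j = r$youden_j, n_pos = r$n_pos, n_neg = r$n_neg)
    }),
    results_full_precision = study$results
  )
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_config(study$config, file.path(dir, "config.json"))
  jsonlite::write_json(study$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report(study, file.path(dir, "report.md"))
  try(write_figures(study, dir), silent = TRUE)
  invisible(dir)
}

write_report <- function(study, path) {
  a <- study$analysis
  lines <- c(
    "# Synthetic Dixon volumetric study report", "",
    sprintf("Subjects: %d MUFA, %d multifactorial; seed %d.",
            study$config$n_per_arm[["mufa"]],
            study$config$n_per_arm[["multifactorial"]], study$config$seed),
    "", "## Spearman correlations",
    knit_simple_table(a$correlations[c("comparison", "estimate", "p_value", "n")]),
    "", "## Bland-Altman agreement",
    knit_simple_table(a$agreement),
    "", "## Between-arm rank-sum tests on changes",
    knit_simple_table(a$change_tests[c("measure", "quantity", "p_value")]),
    "")
  if (!is.null(a$roc$voi)) {
    lines <- c(lines, sprintf(
      "ROC vs MRS labels (cutoff %.2f%%): VOI AUC %.3f (Youden %.2f%%)%s.",
      a$steatosis_cutoff, a$roc$voi$auc, a$roc$voi$youden_threshold,
      if (!is.null(a$roc$wl)) sprintf(", WL AUC %.3f (Youden %.2f%%)",
                                      a$roc$wl$auc, a$roc$wl$youden_threshold)
      else ""))
  }
  writeLines(lines, path)
  invisible(path)
}

knit_simple_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, 4)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

write_figures <- function(study, dir) {
  a <- study$analysis
  save_plot <- function(p, name) {
    ggplot2::ggsave(file.path(dir, name), p, width = 5, height = 4, dpi = 150)
  }
  if (!is.null(a$bland_altman$voi_vs_mrs)) {
    save_plot(autoplot(a$bland_altman$voi_vs_mrs), "bland_altman_voi_mrs.png")
  }
  if (!is.null(a$roc$voi)) {
    save_plot(autoplot(a$roc$voi), "roc_voi.png")
  }
  save_plot(plot_lv_changes(a$changes), "lv_changes.png")
  invisible(NULL)
}

#' Serialize / restore a generator configuration as JSON
#'
#' Lossless round trip: `read_config(write_config(cfg, path))` rebuilds
#' an identical configuration, acquisition constants included.
#'
#' @param config A [generator_config()].
#' @param path JSON file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `generator_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$mrs_constants <- unclass(x$mrs_constants)
  # keep key names on scalar-valued vectors (jsonlite drops vector names)
  x$n_per_arm <- as.list(x$n_per_arm)
  x$arm_effects <- purrr::map(x$arm_effects, function(e) {
    list(baseline = as.list(e$baseline), change = as.list(e$change))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    n_per_arm = unlist(x$n_per_arm), grid_shape = x$grid_shape,
    voxel_size = x$voxel_size,
    arm_effects = purrr::map(x$arm_effects, function(e) {
      list(baseline = unlist(e$baseline), change = unlist(e$change))
    }),
    effect_scale = x$effect_scale, lv_threshold = x$lv_threshold,
    within_field_sd = x$within_field_sd,
    correlation_length = x$correlation_length,
    method_bias = x$method_bias, method_noise_sd = x$method_noise_sd,
    image_noise_sd = x$image_noise_sd, proton_density = x$proton_density,
    voi_side = x$voi_side, thresholds = x$thresholds,
    mrs_constants = do.call(acquisition_constants, as.list(x$mrs_constants)),
    seed = x$seed
  )
}
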