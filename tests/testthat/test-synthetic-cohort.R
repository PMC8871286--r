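test_that("liver masks are non-trivial, deterministic and border-free", {
  m1 <- generate_liver_mask(c(32, 32, 20), c(1, 1, 1), seed = 1)
  expect_true(all(m1$values %in% c(0, 1)))
  expect_gt(sum(m1$values), 0)
  expect_lt(sum(m1$values), prod(dim(m1$values)))
  m1b <- generate_liver_mask(c(32, 32, 20), c(1, 1, 1), seed = 1)
  expect_identical(m1$values, m1b$values)
  m2 <- generate_liver_mask(c(32, 32, 20), c(1, 1, 1), seed = 2)
  expect_false(identical(m1$values, m2$values))
  # minimal grid: interior occupancy only, border slabs all zero
  m3 <- generate_liver_mask(c(8, 8, 8), c(1, 1, 1), seed = 7)
  expect_gt(sum(m3$values), 0)
  expect_true(all(m3$values[c(1, 8), , ] == 0))
  expect_true(all(m3$values[, c(1, 8), ] == 0))
  expect_true(all(m3$values[, , c(1, 8)] == 0))
  expect_error(generate_liver_mask(c(7, 8, 8), c(1, 1, 1), seed = 1),
               class = "dixonvol_sizing_error")
})

test_that("liver masks are 6-connected", {
  for (s in 1:5) {
    m <- generate_liver_mask(c(16, 16, 12), c(2, 2, 2), seed = s)
    expect_true(is_connected6(m$values))
  }
})

test_that("PDFF fields honour mean, spread and clipping contracts", {
  mask <- generate_liver_mask(c(16, 16, 12), c(2, 2, 2), seed = 3)
  inside <- mask$values == 1
  # zero variance -> constant field at the target
  f0 <- generate_pdff_field(mask, 12, within_field_sd = 0, seed = 1)
  expect_true(all(f0$map$values[inside] == 12))
  # zero target -> all-zero field (clip floor)
  fz <- generate_pdff_field(mask, 0, within_field_sd = 4, seed = 1)
  expect_true(all(fz$map$values == 0))
  # masked mean within 0.1 of target, verified by brute-force loop
  f1 <- generate_pdff_field(mask, 10, within_field_sd = 4,
                            correlation_length = 12, seed = 3)
  expect_lt(abs(mean_oracle(f1) - 10), 0.1)
  expect_true(all(f1$map$values >= 0 & f1$map$values <= 100))
  expect_error(generate_pdff_field(mask, 105), class = "dixonvol_domain_error")
})

test_that("spatial autocorrelation increases with correlation length", {
  mask <- vol_grid(array(1, c(24, 24, 12)), c(1, 1, 1))
  lag1 <- function(fld) {
    v <- fld$map$values
    cor(as.vector(v[-24, , ]), as.vector(v[-1, , ]))
  }
  rough <- generate_pdff_field(mask, 30, 8, correlation_length = 0, seed = 5)
  smooth <- generate_pdff_field(mask, 30, 8, correlation_length = 4, seed = 5)
  expect_gt(lag1(smooth), lag1(rough) + 0.3)
})

test_that("Dixon rendering follows the noiseless signal relations", {
  shape <- c(8, 8, 6)
  mk <- function(v) vol_grid(array(v, shape))
  # 0% voxel
  im0 <- render_dixon_images(mk(0), proton_density = 1000)
  expect_equal(unique(as.vector(im0$water$values)), 1000)
  expect_equal(unique(as.vector(im0$fat$values)), 0)
  expect_equal(unique(as.vector(im0$in_phase$values)), 1000)
  expect_equal(unique(as.vector(im0$opposed_phase$values)), 1000)
  # 50% voxel: perfect cancellation in the opposed phase
  im50 <- render_dixon_images(mk(50), proton_density = 1000)
  expect_equal(unique(as.vector(im50$opposed_phase$values)), 0)
  # 20% at proton density 1000 -> (800, 200, 1000, 600)
  im20 <- render_dixon_images(mk(20), proton_density = 1000)
  expect_equal(unique(as.vector(im20$water$values)), 800)
  expect_equal(unique(as.vector(im20$fat$values)), 200)
  expect_equal(unique(as.vector(im20$in_phase$values)), 1000)
  expect_equal(unique(as.vector(im20$opposed_phase$values)), 600)
  # noisy channels stay non-negative
  imn <- render_dixon_images(mk(2), proton_density = 10, image_noise_sd = 20,
                             seed = 9)
  for (ch in imn) expect_true(all(ch$values >= 0))
  expect_error(render_dixon_images(mk(20), proton_density = -1),
               class = "dixonvol_domain_error")
})

test_that("simulated MRS signals invert exactly through mrs_pdff", {
  mask <- vol_grid(array(1, c(10, 10, 10)), c(2, 2, 2))
  voi <- voi_spec(c(9, 9, 9), side = 8)
  for (f in c(0, 0.05, 0.10, 0.25, 0.50)) {
    truth <- pdff_map(vol_grid(array(100 * f, c(10, 10, 10)), c(2, 2, 2)),
                      mask)
    m <- simulate_mrs_signals(truth, voi)
    expect_equal(mrs_pdff(m), 100 * f, tolerance = 1e-10)
  }
  # symmetric relaxation constants at f = 0.5 give equal raw amplitudes
  acq_sym <- acquisition_constants(T2w = 40, T2f = 40, T1w = 600, T1f = 600)
  truth50 <- pdff_map(vol_grid(array(50, c(10, 10, 10)), c(2, 2, 2)), mask)
  m50 <- simulate_mrs_signals(truth50, voi, acq = acq_sym)
  expect_equal(m50$Sf_raw, m50$Sw_raw, tolerance = 1e-12)
  # VOI that misses the mask
  holed <- mask
  holed$values[] <- 0; holed$values[2, 2, 2] <- 1
  truth_h <- pdff_map(vol_grid(array(10, c(10, 10, 10)), c(2, 2, 2)), holed)
  expect_error(simulate_mrs_signals(truth_h, voi_spec(c(16, 16, 16), 2)),
               class = "dixonvol_placement_error")
})

test_that("subject-level draws match the configured distributions", {
  # calibration fidelity at n = 10,000 per arm, within 3 standard errors
  cfg <- generator_config(n_per_arm = 10000, effect_scale = "lv", seed = 123)
  eff <- draw_subject_effects(cfg)
  for (arm_name in c("mufa", "multifactorial")) {
    tgt <- cfg$arm_effects[[arm_name]]
    e <- eff[eff$arm == arm_name, ]
    n <- nrow(e)
    for (q in c("baseline", "change")) {
      m_tgt <- tgt[[q]][["mean"]]; s_tgt <- tgt[[q]][["sd"]]
      expect_lt(abs(mean(e[[q]]) - m_tgt), 3 * s_tgt / sqrt(n))
      expect_lt(abs(sd(e[[q]]) - s_tgt), 3 * s_tgt / sqrt(2 * n))
    }
  }
})

test_that("out-of-range draw pairs are translated, preserving the change", {
  p <- dixonvol:::shift_pair_into_range(105, 105 - 17.61, 0.2, 99.8)
  expect_equal(p[["baseline"]], 99.8)
  expect_equal(p[["week8"]] - p[["baseline"]], -17.61)
  q <- dixonvol:::shift_pair_into_range(-3, -3 + 6, 0, 100)
  expect_equal(q[["baseline"]], 0)
  expect_equal(q[["week8"]] - q[["baseline"]], 6)
  r <- dixonvol:::shift_pair_into_range(50, 47, 0, 100)
  expect_equal(unname(r), c(50, 47))
})

test_that("cohorts are reproducible and conserve ground truth", {
  cfg <- quick_config(n = 2, seed = 42)
  ch <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch$true_mean_pdff, ch2$true_mean_pdff)
  expect_identical(ch$true_lv, ch2$true_lv)
  expect_identical(ch$truth[[1]]$map$values, ch2$truth[[1]]$map$values)
  # declared true LV% equals brute-force recount on the stored field
  for (i in seq_len(nrow(ch))) {
    stored <- ch$true_lv[[i]]
    for (j in seq_along(cfg$thresholds)) {
      expect_equal(unname(stored[j]),
                   lv_oracle(ch$truth[[i]], cfg$thresholds[j]))
    }
    expect_true(all(ch$truth[[i]]$map$values >= 0 &
                      ch$truth[[i]]$map$values <= 100))
    expect_true(all(ch$truth[[i]]$mask$values %in% c(0, 1)))
  }
})

test_that("a zero change distribution pins week8 targets to baseline", {
  cfg <- quick_config(
    n = 2, seed = 5,
    arm_effects = list(
      mufa = list(baseline = c(mean = 10, sd = 3), change = c(mean = 0, sd = 0)),
      multifactorial = list(baseline = c(mean = 10, sd = 3),
                            change = c(mean = 0, sd = 0))))
  ch <- simulate_cohort(cfg, keep_volumes = FALSE)
  wide <- tidyr::pivot_wider(ch[c("subject_id", "timepoint", "target_mean_pdff")],
                             names_from = "timepoint",
                             values_from = "target_mean_pdff")
  expect_equal(wide$week8, wide$baseline)
  # realized masked means then agree within the recentering tolerance
  widem <- tidyr::pivot_wider(ch[c("subject_id", "timepoint", "true_mean_pdff")],
                              names_from = "timepoint",
                              values_from = "true_mean_pdff")
  expect_equal(widem$week8, widem$baseline, tolerance = 0.05)
})

test_that("cohort files round-trip through NIfTI and the manifest", {
  cfg <- quick_config(n = 2, seed = 8)
  ch <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(ch, dir)
  expect_equal(nrow(manifest), nrow(ch))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "generator_config.json")))
  tr <- read_volume(manifest$truth[1])
  expect_equal(tr$values, ch$truth[[1]]$map$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tr$voxel_size, cfg$voxel_size, tolerance = 1e-6)
})

test_that("generator configuration rejects invalid settings", {
  expect_error(generator_config(n_per_arm = 1),
               class = "dixonvol_config_error")
  expect_error(generator_config(grid_shape = c(8, 8, 4)),
               class = "dixonvol_config_error")
  expect_error(generator_config(within_field_sd = -1),
               class = "dixonvol_config_error")
  expect_error(generator_config(thresholds = numeric(0)),
               class = "dixonvol_config_error")
  expect_error(generator_config(effect_scale = "lv", within_field_sd = 0),
               class = "dixonvol_config_error")
})
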