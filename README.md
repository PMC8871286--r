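# dixonvol

Whole-liver Dixon MRI volumetrics for hepatic steatosis.

`dixonvol` is for imaging scientists and biostatisticians quantifying
liver fat in intervention studies. It implements the full analysis
chain around a volumetric steatosis statistic:

* **Dixon fat mapping** — two-point water/fat separation from
  in-phase/opposed-phase magnitude images (`separate_two_point()`),
  voxel-wise signal fat-fraction maps
  (`fat_fraction_map()`: PDFF(%) = 100·F/(F+W)), cubic VOI placement
  colocalised with the MRS voxel (`place_voi()`), and regional means
  (`mean_pdff()`).
* **MRS quantification** — PDFF from water/lipid peak amplitudes with
  T2-decay and T1-saturation correction,
  S<sup>corr</sup> = S<sup>raw</sup> / (e^(−TE/T2)·(1 − e^(−TR/T1))),
  then PDFF(%) = 100·S_f/(S_f + S_w) (`mrs_pdff()`).
* **Volumetrics** — the core statistic
  LV%\_TH = 100·#{voxels in liver with PDFF > TH}/#{liver voxels}
  (`lv_percent_above()`), the percentage of liver volume above a
  steatosis threshold (5.56% conventional cutoff; protocol-specific
  cutoffs derived by ROC/Youden analysis against MRS labels,
  `roc_youden()`).
* **Cohort statistics** — Spearman correlation, Bland–Altman limits of
  agreement, paired Wilcoxon signed-rank, Wilcoxon rank-sum on paired
  changes and percent changes, and two-way repeated-measures ANOVA
  (diet × time).
* **A synthetic cohort generator** — seeded paired two-arm cohorts of
  3D liver phantoms (deformed-ellipsoid masks, spatially correlated
  true PDFF fields, Dixon renderings, MRS signals) with known ground
  truth, calibrated to realistic fatty-liver effect sizes, so the
  entire pipeline is testable end to end without patient data.

Everything cohort-level is tibble-first and pipeable; fitted results
have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a 39-subject two-arm dietary study (21 MUFA, 18
multifactorial) with the LV%-calibrated generator and run the full
analysis:

```r
library(dixonvol)

cfg   <- generator_config(effect_scale = "lv", seed = 2)
study <- run_study(cfg)
study
#> <dixon_study> 39 subjects (21 MUFA / 18 multifactorial), seed 2
#> <dixon_analysis>
#> Correlations (Spearman):
#>  comparison  estimate      p_value
#>  voi_vs_mrs 0.8013138 1.247432e-18
#>   wl_vs_mrs 0.7391009 1.109655e-14
#>   voi_vs_wl 0.9118603 4.082348e-31
#> Bland-Altman agreement:
#>  comparison  n          md  sd_diff loa_lower loa_upper
#>  voi_vs_mrs 78  1.82445691 2.484898 -3.045943  6.694857
#>   wl_vs_mrs 78  1.87824802 2.763199 -3.537621  7.294117
#>   voi_vs_wl 78 -0.05379111 1.013449 -2.040151  1.932569
#> ROC (VOI scores): AUC 0.916, Youden threshold 7.119%
#> ROC (WL scores):  AUC 0.921, Youden threshold 7.973%
```

The MRI-PDFF measurements correlate strongly with MRS-PDFF (ρ ≈ 0.8
over 78 subject-timepoints) and overestimate it systematically by
about 1.8 %-points — the generator's injected inter-method bias —
with 95% limits of agreement spanning roughly −3 to +7 %-points. The
ROC analysis, using MRS-PDFF > 5.56% as the steatosis label, finds
operating thresholds near 7–8% for the MRI measurements.

The volumetric endpoint — how the percentage of liver above the 5.56%
cutoff changed over 8 weeks, per arm:

```r
dplyr::filter(study$summary, measure == "lv_5.56")
#>              arm timepoint measure  n     mean       sd
#> 1           mufa  baseline lv_5.56 21 76.91437 19.43278
#> 2           mufa     week8 lv_5.56 21 67.51338 24.37192
#> 3 multifactorial  baseline lv_5.56 18 74.15071 20.71218
#> 4 multifactorial     week8 lv_5.56 18 54.51572 27.90639

dplyr::filter(study$analysis$change_tests, measure == "lv_5.56")[
  c("measure", "quantity", "statistic", "p_value")]
#>   measure       quantity statistic    p_value
#> 1 lv_5.56         change       267 0.02901261
#> 2 lv_5.56 percent_change       264 0.03583456
```

Both arms start with about three quarters of the liver above the
cutoff; after 8 weeks the multifactorial arm has lost ~20 %-points of
steatotic volume against ~9 in the MUFA arm, and the rank-sum test
finds the between-arm difference significant (p ≈ 0.03) for both the
absolute and the percent change.

Lower-level pieces compose directly:

```r
mask  <- generate_liver_mask(c(32, 32, 20), c(2, 2, 2), seed = 1)
truth <- generate_pdff_field(mask, target_mean = 10, within_field_sd = 4)
im    <- render_dixon_images(truth, proton_density = 1000)
ws    <- separate_two_point(im$in_phase, im$opposed_phase)
map   <- fat_fraction_map(ws$water, ws$fat, mask)
lv_percent_above(map, c(5.56, 7.97, 8.8))
```

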