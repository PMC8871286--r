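---
title: "Whole-liver Dixon volumetrics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-liver Dixon volumetrics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dixonvol)
```

## The problem

Hepatic steatosis — excess triglyceride in the liver — is usually
quantified non-invasively in one of two ways. Single-voxel MR
spectroscopy (MRS) measures the water and lipid resonance peaks in one
small volume and is treated as the non-invasive reference standard, but
it samples only a few cm³ of an organ whose fat content is spatially
heterogeneous. Chemical-shift (Dixon) MRI covers the whole liver and
yields a voxel-wise *signal fat-fraction* map, from which the
conventional summary is a mean PDFF over a region of interest or the
whole organ.

This package implements a volumetric alternative: **LV%**, the
percentage of liver volume whose PDFF exceeds a steatosis threshold.
Averaging collapses the spatial distribution of fat; LV% retains it,
asking "how much of the liver is steatotic?" rather than "how fatty is
the liver on average?". The package provides the full chain needed to
compute and evaluate this statistic — Dixon water/fat separation,
fat-fraction mapping, MRS quantification with relaxation correction, VOI
colocalisation, LV% volumetrics, and the two-arm paired statistics of a
dietary intervention design — together with a synthetic cohort generator
that makes the whole chain testable without patient data.

## Signal models

### Dixon imaging

A two-point Dixon acquisition provides in-phase (IP) and opposed-phase
(OP) magnitude composites of the water (W) and fat (F) signals:

$$IP = W + F, \qquad OP = |W - F|.$$

Under the water-dominant convention the separation inverts these as
$W = (IP + OP)/2$, $F = (IP - OP)/2$, and the voxel-wise signal
fat-fraction is

$$\mathrm{PDFF}(\%) = 100 \cdot \frac{F}{F + W}.$$

No phase information is modelled, so voxels with true fat fraction
above 50% are mis-separated (water and fat swap). This is a known
property of magnitude-only two-point Dixon; the map is therefore a
*signal* fat-fraction, not a confounder-corrected proton-density fat
fraction, and the round-trip accuracy of the implementation is asserted
only for voxels below 50% — the regime of liver parenchyma in the
intended population. T1/T2* bias, multi-peak fat spectral modelling and
phase unwrapping are deliberately out of scope.

### MRS quantification

The MRS measurement consists of a water peak amplitude $S_w$ and the
summed lipid peak amplitude $S_f$ (peaks at 1.3, 0.9 and 1.6 ppm). Raw
amplitudes are attenuated by transverse decay over the echo time and
incomplete longitudinal recovery over the repetition time; the package
corrects each species with the standard steady-state factor

$$S^{\mathrm{corr}} = \frac{S^{\mathrm{raw}}}
 {e^{-TE/T_2}\,\bigl(1 - e^{-TR/T_1}\bigr)},$$

then forms $\mathrm{PDFF}(\%) = 100\,S_f/(S_f + S_w)$ from the corrected
amplitudes. Defaults are TE = 35 ms, TR = 3000 ms, and liver relaxation
times $T_2$ = 30/52 ms, $T_1$ = 990/402 ms for water/fat. Two choices
here were genuinely open and are worth recording:

* the exact saturation-correction formula is a convention; the
  steady-state factor $(1 - e^{-TR/T_1})$ is the standard choice for
  PRESS at long TR, and the constants are arguments, so other
  conventions can be swapped in;
* correction is applied to the raw amplitudes *before* forming the
  ratio, and to the summed lipid signal with a single fat $T_1/T_2$
  pair (one relaxation pair per species is all that is specified for
  this protocol).

The simulator synthesises raw amplitudes by applying the same decay
factors forward, so in the noiseless case quantification inverts
simulation exactly — this round trip is asserted in the test suite at
fat fractions from 0 to 50%.

### The volumetric statistic

For a PDFF map $M$ with liver mask $\Omega$ and threshold $TH$,

$$\mathrm{LV\%}_{TH} = 100 \cdot
  \frac{\#\{v \in \Omega : M(v) > TH\}}{\#\Omega}.$$

"Above" is implemented as a strict inequality: a voxel exactly at the
threshold is not steatotic. This is the literal reading of the
definition; a `ge = TRUE` flag provides the $\geq$ variant for
sensitivity analysis. The default threshold set is
$\{5.56, 7.97, 8.8\}$%: 5.56% is the conventional cutoff separating
normal from fatty liver, and the other two are protocol-specific
cutoffs of the kind derived by the package's own ROC/Youden machinery
from MRS-based labels. LV% is computed on the whole-liver map only;
restricting it to the VOI would mostly measure VOI placement, not organ
coverage.

## Statistics

The statistical layer mirrors a paired two-arm dietary design:

* **Spearman correlation** between the MRI and MRS PDFF measurements
  (mid-ranks on ties, two-sided p from the t approximation).
* **Bland–Altman agreement**: mean difference (MD) of paired
  measurements and 95% limits of agreement $MD \pm 1.96\,SD$. The
  limits are symmetric about MD by construction, which also allows
  reconstruction of a missing limit from published summary values
  (`bland_altman_limits()`).
* **Paired Wilcoxon signed-rank** per arm on 8-week − baseline
  changes. Zero differences are dropped and tallied; the exact null
  distribution is used for $n \le 25$ without ties, otherwise the
  normal approximation with continuity and tie correction.
* **Wilcoxon rank-sum** between arms on changes and percent changes,
  exact for combined $n \le 20$ without ties. The fixed switchover
  points make p-values reproducible across platforms.
* **Two-way repeated-measures ANOVA** (diet × time) via the standard
  mixed decomposition: diet tested against the between-subject stratum,
  time and diet × time against the subject-by-time residual.
* **ROC/Youden threshold derivation**: MRS-PDFF > 5.56% defines the
  steatosis label; MRI-PDFF scores are swept over candidate thresholds
  (midpoints between adjacent distinct scores, plus infinite
  sentinels); AUC is the trapezoidal area, identical to the normalised
  Mann–Whitney U (asserted against the rank-sum statistic in the test
  suite); the operating threshold maximises $J = $ sensitivity +
  specificity − 1, ties broken toward the lowest threshold for
  determinism.

No multiplicity adjustment is applied, matching the single-endpoint
reporting convention of the design the package supports
($\alpha = 0.05$ throughout). Percent change uses each subject's own
baseline as denominator; subjects with a zero baseline keep their
absolute change but are excluded (flagged and counted) from
percent-change statistics.

## The synthetic cohort generator

Real patient images for this design are not publicly available, so the
generator is a first-class module: it defines the conditions under
which every downstream claim is tested.

Each subject receives:

1. **A liver mask**: a randomly deformed ellipsoid (smooth bounded
   perturbation of the boundary), trimmed to the lattice interior and
   reduced to its connected component. Only connectedness,
   non-triviality and border clearance matter for the statistic, so no
   anatomical detail is modelled.
2. **A true PDFF field per timepoint**: white noise smoothed at the
   configured correlation length (default 8 mm), standardised over the
   mask, scaled to the within-liver SD (default 2.5 %-points), added to
   the subject's target mean, then iteratively recentred and clipped so
   the masked mean lands within 0.1 %-points of target inside
   [0, 100]. Degenerate targets (0 or 100%) yield the constant field,
   the only field with that mean in range.
3. **Dixon renderings**: the noiseless signal relations above at a
   proton density of 1000 signal units, with independent Gaussian noise
   (default SD 5) added to the water and fat channels *before*
   composing IP/OP, floored at zero. Additive Gaussian noise on the
   component channels was chosen over Rician noise on the magnitude
   composites: magnitude-bias modelling is out of scope, and the
   simpler model keeps the noiseless round trip exact.
4. **MRS amplitudes** from a 20 mm cube (shrunk on small test lattices)
   at the masked-voxel nearest the mask centroid, with the forward
   relaxation decay applied. Between-method structure is injected here:
   the MRS-side fat fraction is the true VOI mean minus a bias (default
   2.07 %-points) plus Gaussian disagreement noise (default SD
   2.56 %-points), so the MRI-minus-MRS comparison exhibits realistic
   Bland–Altman structure. Because PDFF is floored at zero, subjects
   with very low fat compress the observed bias slightly below its
   nominal value — a floor effect the agreement analysis inherits, as
   it would with real data.

### Arm-level calibration

Subject-level effects are drawn per arm as (baseline, paired change)
pairs, and the 8-week value is always `baseline + change` with an
independent change draw. The within-subject correlation is therefore
induced structurally rather than via a free correlation parameter —
this matches the arm-level change mean/SD directly, which is the
quantity the downstream comparisons consume.

Two calibration presets ship with the generator:

* `"pdff"` (default): mean-PDFF draws — baseline 9.47 ± 8.89% (MUFA)
  and 9.18 ± 7.78% (multifactorial); changes −1.4 ± 2.7 and
  −4.0 ± 4.5 %-points.
* `"lv"`: LV%₅.₅₆ draws — baseline 73.95 ± 21.95 and 73.64 ± 19.85;
  changes −6.66 ± 11.06 and −17.61 ± 13.43 %-points. An LV target is
  mapped to a mean-PDFF target through the Gaussian field model:
  $\mathrm{LV}/100 = \Phi\!\bigl((\mu - TH)/\sigma\bigr)$, inverted
  for $\mu$.

Two consequences of modelling bounded quantities with Gaussian draws
deserve explicit documentation:

* **Boundary handling preserves the paired change.** A Gaussian
  baseline draw occasionally overflows the representable range
  (LV > 100%). Clipping each timepoint independently would bias the
  realized change mean by roughly +0.9 %-points at the LV calibration
  — a ceiling artefact, not a property of the intervention. Instead
  the (baseline, week8) *pair* is translated back into range, keeping
  the change — the calibration target — intact; residual clipping
  applies only when a pair's span itself exceeds the range.
* **The attainable mean LV% has a ceiling under Gaussian PDFF draws.**
  With baseline mean-PDFF draws of roughly 9 ± 8% the cohort-mean
  LV%₅.₅₆ cannot exceed about 68% for any within-liver SD, whereas
  fatty-liver cohorts show ~74%: real PDFF distributions are
  right-skewed. The default within-liver SD of 2.5 %-points was chosen
  as realistic tissue heterogeneity; the `"lv"` preset sidesteps the
  ceiling by drawing LV targets directly. Passing tests on this
  generator therefore demonstrate correct *mechanics* (mapping,
  counting, statistics, recovery of injected effects) — not that
  Gaussian cohorts reproduce every marginal feature of real ones.

Calibration fidelity is asserted on the *drawn* subject-level effects
(`draw_subject_effects()`, 10,000 per arm, within 3 standard errors);
after field synthesis and per-voxel clipping the realized summaries
necessarily carry small truncation effects, which is precisely why the
draws and the realizations are kept distinguishable in the cohort
table.

### Reproducibility

One cohort seed drives everything. Subject streams are forked from it
arithmetically (an LCG-style step on the 31-bit integer ring, indexed
by subject position), so a cohort is byte-identical across runs and
does not depend on evaluation order; the generator draws all arm
effects first, which is what makes the large-n calibration checks
possible without rendering a single image. Every `run_study()` output
directory carries a provenance record (package version, seed, config
hash) and the config itself round-trips losslessly through JSON.

## Numerical choices and degenerate inputs

* PDFF is carried in percent (0–100) everywhere; rounding to two
  decimals happens only in CSV output, with full-precision JSON
  sidecars.
* VOI membership is a closed-cube, voxel-centre test — unambiguous,
  and on lattices whose voxel boundaries align with the cube faces it
  reproduces the nominal cube volume exactly. Lattices are axis-aligned
  RAS+; oblique affines are out of scope.
* Voxels with zero total Dixon signal get PDFF 0 and are counted;
  noise-negative fat signals are floored at zero and tallied.
* All-zero paired differences, single-class labels, constant vectors
  and incomplete designs raise typed errors rather than silent NAs;
  inside the full-cohort analysis, degenerate cells are reported as NA
  rows so one pathological measure cannot abort a study.
* Field recentring iterates clip-and-shift to a 0.01 %-point tolerance
  with a 200-iteration cap.

## Problem sizes used in the shipped checks

The test suite exercises phantom grids from 8³ up to 32×32×20 voxels,
and the parameter-recovery study runs 100 replicates of 500 subjects
per arm on 10×10×8 lattices at 3 mm isotropic spacing — small grids
chosen so the per-subject LV% measurement noise (~10 %-points, from the
limited number of independent correlated-field patches in a small
liver) still leaves the calibrated arm separation detectable with
essentially unit power at those sample sizes. Type-I error of the
rank-sum comparison is checked over 2,000 null cohorts at the trial's
21/18 allocation.

## Known limitations

* Magnitude-only two-point separation: no fat-dominant voxels, no
  field-inhomogeneity, T2* or multi-peak fat modelling.
* The generator's Gaussian fields and masks emulate statistical, not
  anatomical, structure: no vessels, no segmentation error, no
  breathing or registration artefacts between timepoints.
* MRS simulation starts from peak amplitudes; spectral fitting is out
  of scope (a toy trapezoidal integrator is provided for synthetic
  spectra only).
* The statistics assume complete pairs; there is no missing-data
  machinery beyond explicit errors.
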