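#' MRS acquisition and relaxation constants
#'
#' Echo time, repetition time and the species-specific relaxation times
#' used to correct water and lipid peak amplitudes for T2 decay and T1
#' saturation. Defaults are the single-voxel PRESS settings and literature
#' liver relaxation times used in the study design this package supports:
#' TE = 35 ms, TR = 3000 ms, T2 water/fat = 30/52 ms, T1 water/fat =
#' 990/402 ms.
#'
#' @param TE Echo time (ms).
#' @param TR Repetition time (ms); must exceed `TE`.
#' @param T2w,T2f Transverse relaxation times of water and fat (ms).
#' @param T1w,T1f Longitudinal relaxation times of water and fat (ms).
#' @return An object of class `acq_constants`.
#' @examples
#' acquisition_constants()
#' @export
acquisition_constants <- function(TE = 35, TR = 3000,
                                  T2w = 30, T2f = 52,
                                  T1w = 990, T1f = 402) {
  vals <- c(TE = TE, TR = TR, T2w = T2w, T2f = T2f, T1w = T1w, T1f = T1f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All acquisition constants must be strictly positive and finite.",
          class = "dixonvol_domain_error")
  }
  if (TE >= TR) {
    abort("`TE` must be smaller than `TR`.", class = "dixonvol_domain_error")
  }
  structure(as.list(vals), class = "acq_constants")
}

#' @export
print.acq_constants <- function(x, ...) {
  cat(sprintf(
    "<acq_constants> TE %g ms, TR %g ms | T2 w/f %g/%g ms | T1 w/f %g/%g ms\n",
    x$TE, x$TR, x$T2w, x$T2f, x$T1w, x$T1f))
  invisible(x)
}

#' Single-voxel MRS measurement
#'
#' Raw water and summed-lipid peak amplitudes (the lipid signal is the sum
#' of the peaks at 1.3, 0.9 and 1.6 ppm) together with the acquisition
#' constants needed for relaxation correction.
#'
#' @param Sw_raw Water peak amplitude (arbitrary signal units, >= 0).
#' @param Sf_raw Summed lipid peak amplitude (same units, >= 0).
#' @param acq An [acquisition_constants()] object.
#' @return An object of class `mrs_measurement`.
#' @export
mrs_measurement <- function(Sw_raw, Sf_raw, acq = acquisition_constants()) {
  stopifnot(inherits(acq, "acq_constants"))
  if (!is.numeric(Sw_raw) || !is.numeric(Sf_raw) ||
      length(Sw_raw) != 1L || length(Sf_raw) != 1L ||
      !is.finite(Sw_raw) || !is.finite(Sf_raw) ||
      Sw_raw < 0 || Sf_raw < 0) {
    abort("Peak amplitudes must be single finite non-negative numbers.",
          class = "dixonvol_domain_error")
  }
  if (Sw_raw == 0 && Sf_raw == 0) {
    abort("Water and lipid amplitudes cannot both be zero.",
          class = "dixonvol_measurement_error")
  }
  structure(list(Sw_raw = Sw_raw, Sf_raw = Sf_raw, acq = acq),
            class = "mrs_measurement")
}

#' @export
print.mrs_measurement <- function(x, ...) {
  cat(sprintf("<mrs_measurement> Sw %.4g, Sf %.4g (raw) -> PDFF %.2f%%\n",
              x$Sw_raw, x$Sf_raw, mrs_pdff(x)))
  invisible(x)
}

#' Correct a peak amplitude for T2 decay and T1 saturation
#'
#' Divides the measured amplitude by the steady-state signal attenuation
#' `exp(-TE/T2) * (1 - exp(-TR/T1))`, undoing transverse decay at the echo
#' time and incomplete longitudinal recovery at the repetition time. The
#' correction is linear in the amplitude and always increases it.
#'
#' @param amplitude_raw Measured amplitude (>= 0).
#' @param TE,TR Echo and repetition time (ms).
#' @param T1,T2 Relaxation times of the species being corrected (ms).
#' @return Corrected amplitude on the same arbitrary scale.
#' @examples
#' relaxation_correct(1, TE = 35, TR = 3000, T1 = 402, T2 = 52)
#' @export
relaxation_correct <- function(amplitude_raw, TE, TR, T1, T2) {
  if (any(!is.finite(c(TE, TR, T1, T2))) || any(c(TE, TR, T1, T2) <= 0)) {
    abort("TE, TR, T1 and T2 must be strictly positive.",
          class = "dixonvol_domain_error")
  }
  if (any(amplitude_raw < 0)) {
    abort("`amplitude_raw` must be non-negative.",
          class = "dixonvol_domain_error")
  }
  att <- exp(-TE / T2) * (1 - exp(-TR / T1))
  amplitude_raw / att
}

#' MRS proton-density fat fraction
#'
#' Applies [relaxation_correct()] to the raw lipid and water amplitudes
#' (with their species-specific constants) and returns
#' `100 * Sf / (Sf + Sw)` in percent. Invariant under common rescaling of
#' the two raw amplitudes and strictly increasing in the lipid amplitude.
#'
#' @param m An [mrs_measurement()].
#' @return PDFF in percent (0-100).
#' @examples
#' m <- mrs_measurement(Sw_raw = 0.9, Sf_raw = 0.1)
#' mrs_pdff(m)
#' @export
mrs_pdff <- function(m) {
  stopifnot(inherits(m, "mrs_measurement"))
  a <- m$acq
  Sf <- relaxation_correct(m$Sf_raw, a$TE, a$TR, a$T1f, a$T2f)
  Sw <- relaxation_correct(m$Sw_raw, a$TE, a$TR, a$T1w, a$T2w)
  if (Sf + Sw <= 0) {
    abort("Corrected amplitudes sum to zero; PDFF undefined.",
          class = "dixonvol_measurement_error")
  }
  100 * Sf / (Sf + Sw)
}

#' Integrate a toy MRS spectrum into peak amplitudes
#'
#' A deliberately simple peak integrator for synthetic spectra only (full
#' spectral basis fitting is out of scope): each window's amplitude is the
#' trapezoidal area above a straight local baseline drawn between the
#' window endpoints; the lipid windows are summed into `Sf_raw`.
#'
#' @param spectrum Data frame with columns `ppm` and `amplitude`, sampled
#'   on an increasing or decreasing ppm axis covering all windows.
#' @param water_window Length-2 ppm interval for the water peak
#'   (default around 4.7 ppm).
#' @param lipid_windows List of length-2 ppm intervals for the lipid peaks
#'   (defaults around 1.3, 0.9 and 1.6 ppm); must be disjoint from the
#'   water window.
#' @param acq Acquisition constants attached to the resulting measurement.
#' @return An [mrs_measurement()].
#' @export
integrate_toy_spectrum <- function(spectrum,
                                   water_window = c(4.0, 5.4),
                                   lipid_windows = list(c(1.15, 1.45),
                                                        c(0.75, 1.05),
                                                        c(1.45, 1.75)),
                                   acq = acquisition_constants()) {
  stopifnot(is.data.frame(spectrum),
            all(c("ppm", "amplitude") %in% names(spectrum)))
  ppm <- spectrum$ppm
  amp <- spectrum$amplitude
  ord <- order(ppm)
  ppm <- ppm[ord]; amp <- amp[ord]
  rng <- range(ppm)
  wins <- c(list(water_window), lipid_windows)
  for (w in wins) {
    if (length(w) != 2L || min(w) < rng[1] || max(w) > rng[2]) {
      abort("Every window must lie within the sampled ppm range.",
            class = "dixonvol_config_error")
    }
  }
  ww <- sort(water_window)
  for (w in lipid_windows) {
    w <- sort(w)
    if (w[1] < ww[2] && ww[1] < w[2]) {
      abort("Water and lipid windows must be disjoint.",
            class = "dixonvol_config_error")
    }
  }
  area_above_baseline <- function(w) {
    w <- sort(w)
    sel <- ppm >= w[1] & ppm <= w[2]
    if (sum(sel) < 2) return(0)
    x <- ppm[sel]; y <- amp[sel]
    base <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
    z <- y - base
    max(0, sum(diff(x) * (head(z, -1) + tail(z, -1)) / 2))
  }
  Sw <- area_above_baseline(water_window)
  Sf <- sum(vapply(lipid_windows, area_above_baseline, numeric(1)))
  mrs_measurement(Sw_raw = Sw, Sf_raw = Sf, acq = acq)
}
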