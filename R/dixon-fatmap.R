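#' Two-point Dixon water/fat separation
#'
#' Recovers water and fat images from magnitude in-phase and
#' opposed-phase images under the water-dominant convention:
#' `water = (IP + OP) / 2`, `fat = (IP - OP) / 2`. No phase information is
#' modelled, so voxels whose true fat content exceeds 50% are
#' mis-separated (water and fat swap); the returned attribute
#' `n_negative_fat` counts voxels where noise drove the computed fat
#' signal negative before flooring at zero.
#'
#' @param in_phase,opposed_phase Congruent `vol_grid`s with non-negative
#'   values.
#' @return Named list with `water` and `fat` `vol_grid`s; attribute
#'   `n_negative_fat` carries the floored-voxel tally.
#' @examples
#' ip <- vol_grid(array(1000, c(8, 8, 8)))
#' op <- vol_grid(array(600, c(8, 8, 8)))
#' ws <- separate_two_point(ip, op)
#' ws$water$values[1, 1, 1]  # 800
#' @export
separate_two_point <- function(in_phase, opposed_phase) {
  stopifnot(inherits(in_phase, "vol_grid"), inherits(opposed_phase, "vol_grid"))
  check_congruent(in_phase, opposed_phase, "in-phase and opposed-phase images")
  if (any(in_phase$values < 0) || any(opposed_phase$values < 0)) {
    abort("Magnitude images must be non-negative.",
          class = "dixonvol_domain_error")
  }
  water <- (in_phase$values + opposed_phase$values) / 2
  fat <- (in_phase$values - opposed_phase$values) / 2
  n_neg <- sum(fat < 0)
  fat[fat < 0] <- 0
  out <- list(
    water = vol_grid(water, in_phase$voxel_size, in_phase$origin),
    fat = vol_grid(fat, in_phase$voxel_size, in_phase$origin)
  )
  attr(out, "n_negative_fat") <- n_neg
  out
}

#' Voxel-wise signal fat-fraction map
#'
#' Computes `100 * fat / (fat + water)` per voxel and couples the result
#' with the liver mask. Voxels with zero total signal are set to 0% and
#' counted in the attribute `n_zero_signal`; values are clipped to
#' [0, 100]. The map is invariant under common positive rescaling of the
#' water and fat images.
#'
#' @param water,fat Congruent non-negative `vol_grid`s.
#' @param mask Binary liver mask `vol_grid` on the same lattice.
#' @return A [pdff_map()]; attribute `n_zero_signal` counts flagged voxels.
#' @export
fat_fraction_map <- function(water, fat, mask) {
  stopifnot(inherits(water, "vol_grid"), inherits(fat, "vol_grid"))
  check_congruent(water, fat, "water and fat images")
  check_congruent(water, mask, "images and mask")
  if (any(water$values < 0) || any(fat$values < 0)) {
    abort("Water and fat images must be non-negative.",
          class = "dixonvol_domain_error")
  }
  tot <- water$values + fat$values
  ff <- array(0, dim(tot))
  nz <- tot > 0
  ff[nz] <- 100 * fat$values[nz] / tot[nz]
  ff[ff < 0] <- 0
  ff[ff > 100] <- 100
  out <- pdff_map(vol_grid(ff, water$voxel_size, water$origin), mask)
  attr(out, "n_zero_signal") <- sum(!nz)
  out
}

#' Select the voxels of a cubic VOI
#'
#' A voxel belongs to the VOI iff its centre lies inside the closed
#' axis-aligned cube `[center - side/2, center + side/2]` on every axis.
#' On a lattice whose voxel boundaries align with the cube faces this
#' reproduces the nominal cube volume exactly (e.g. a 20 mm cube on a
#' 1 x 1 x 2 mm lattice selects 20 x 20 x 10 voxels).
#'
#' @param map A [pdff_map()] (provides the lattice).
#' @param voi A [voi_spec()].
#' @return Binary `vol_grid` on the map lattice.
#' @export
place_voi <- function(map, voi) {
  stopifnot(inherits(map, "pdff_map"), inherits(voi, "voi_spec"))
  g <- map$map
  half <- voi$side / 2
  sel <- lapply(1:3, function(ax) {
    x <- axis_coords(g, ax)
    x >= voi$center[ax] - half & x <= voi$center[ax] + half
  })
  m <- array(0, dim(g$values))
  m[sel[[1]], sel[[2]], sel[[3]]] <- 1
  if (sum(m) == 0) {
    abort("VOI cube selects no voxel centre on this lattice.",
          class = "dixonvol_placement_error")
  }
  vol_grid(m, g$voxel_size, g$origin)
}

#' Mean PDFF over a region
#'
#' Arithmetic mean of the map over the intersection of `region` with the
#' map's liver mask.
#'
#' @param map A [pdff_map()].
#' @param region Binary `vol_grid` congruent with the map. Default: the
#'   whole liver mask.
#' @return Mean PDFF in percent.
#' @export
mean_pdff <- function(map, region = NULL) {
  stopifnot(inherits(map, "pdff_map"))
  if (is.null(region)) {
    sel <- map$mask$values == 1
  } else {
    stopifnot(inherits(region, "vol_grid"))
    check_congruent(map$map, region, "map and region")
    sel <- map$mask$values == 1 & region$values == 1
  }
  if (sum(sel) == 0) {
    abort("Region does not intersect the liver mask.",
          class = "dixonvol_region_error")
  }
  mean(map$map$values[sel])
}
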