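#' 3D scalar volume on a regular lattice
#'
#' `vol_grid` is the carrier for every image and map in the package: a 3D
#' numeric array together with its voxel spacing (mm) and the world
#' coordinate of the first voxel centre (mm). Lattices are axis-aligned
#' (RAS+); oblique affines are out of scope.
#'
#' @param values 3D numeric array.
#' @param voxel_size Numeric length-3, spacing per axis in mm (all > 0).
#' @param origin Numeric length-3, world coordinate (mm) of the centre of
#'   voxel (1, 1, 1). Default `c(0, 0, 0)`.
#' @return An object of class `vol_grid`.
#' @examples
#' g <- vol_grid(array(0, c(8, 8, 4)), voxel_size = c(0.98, 0.98, 2))
#' dim(g$values)
#' @export
vol_grid <- function(values, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.", class = "dixonvol_geometry_error")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "dixonvol_geometry_error")
  }
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three strictly positive spacings (mm).",
          class = "dixonvol_geometry_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be three finite world coordinates (mm).",
          class = "dixonvol_geometry_error")
  }
  structure(list(values = values, voxel_size = voxel_size, origin = origin),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vol_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, trim = TRUE), collapse = " x "),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  v <- x$values
  cat(sprintf("  values in [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' Test two volumes for lattice congruence
#'
#' Congruent volumes share shape, voxel spacing and origin, so their voxels
#' correspond one-to-one.
#'
#' @param a,b `vol_grid` objects.
#' @param tol Tolerance (mm) on spacing and origin comparison.
#' @return `TRUE` or `FALSE`.
#' @export
congruent <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "vol_grid"), inherits(b, "vol_grid"))
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_congruent <- function(a, b, what = "volumes") {
  if (!congruent(a, b)) {
    abort(paste0("Lattice mismatch between ", what,
                 " (shape, spacing and origin must agree)."),
          class = "dixonvol_geometry_error")
  }
  invisible(TRUE)
}

#' World coordinates of voxel centres along one axis
#'
#' @param grid A `vol_grid`.
#' @param axis Axis index (1, 2 or 3).
#' @return Numeric vector of voxel-centre coordinates (mm).
#' @export
axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "vol_grid"), axis %in% 1:3)
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$voxel_size[axis]
}

#' Read / write a volume as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()]. The
#' voxel spacing is stored in the header `pixdim` and the origin in the
#' sform translation (RAS+, axis-aligned).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid A `vol_grid` to write.
#' @return `read_volume()` returns a `vol_grid`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vol_grid(as.array(img),
           voxel_size = RNifti::pixdim(img)[1:3],
           origin = aff[1:3, 4])
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "vol_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  aff <- diag(c(grid$voxel_size, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Fat-fraction map with its liver mask
#'
#' Couples a PDFF map (percent units, 0-100) with a binary liver mask on a
#' congruent lattice.
#'
#' @param map `vol_grid` of fat-fraction values in percent.
#' @param mask Binary `vol_grid` (0/1) on the same lattice, non-empty.
#' @return An object of class `pdff_map`.
#' @export
pdff_map <- function(map, mask) {
  stopifnot(inherits(map, "vol_grid"), inherits(mask, "vol_grid"))
  check_congruent(map, mask, "map and mask")
  mv <- mask$values
  if (!all(mv %in% c(0, 1))) {
    abort("`mask` must be binary (0/1).", class = "dixonvol_geometry_error")
  }
  if (sum(mv) == 0) {
    abort("`mask` must be non-empty.", class = "dixonvol_region_error")
  }
  inside <- map$values[mv == 1]
  if (any(inside < -1e-9 | inside > 100 + 1e-9)) {
    abort("PDFF values inside the mask must lie in [0, 100] percent.",
          class = "dixonvol_domain_error")
  }
  structure(list(map = map, mask = mask), class = "pdff_map")
}

#' @export
print.pdff_map <- function(x, ...) {
  n <- sum(x$mask$values)
  inside <- x$map$values[x$mask$values == 1]
  cat(sprintf("<pdff_map> %d masked voxels, PDFF mean %.2f%% (range %.2f-%.2f%%)\n",
              n, mean(inside), min(inside), max(inside)))
  invisible(x)
}

#' Cubic volume of interest specification
#'
#' An axis-aligned cube in world coordinates, used to colocalise the MRI
#' analysis volume with the MRS voxel. The study convention is a 20 mm cube
#' placed in the right lobe.
#'
#' @param center World coordinates (mm) of the cube centre.
#' @param side Edge length (mm), strictly positive. Default 20.
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(center, side = 20) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    abort("`center` must be three finite world coordinates (mm).",
          class = "dixonvol_domain_error")
  }
  if (!is.numeric(side) || length(side) != 1L || side <= 0) {
    abort("`side` must be a single positive edge length (mm).",
          class = "dixonvol_domain_error")
  }
  structure(list(center = center, side = side), class = "voi_spec")
}

# Run code with a locally-set RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
# Kernel rows are renormalised at the edges so constants are preserved.
smooth_gaussian_3d <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- d[ax]
    r <- min(n - 1L, max(1L, ceiling(3 * s)))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * s^2))
      w[abs(i - j) > r] <- 0
      w
    })
    K <- K / rowSums(K)
    arr <- apply_along_axis(arr, ax, K)
  }
  arr
}

# Multiply a 3D array by matrix K along one axis (K is n_ax x n_ax).
apply_along_axis <- function(arr, ax, K) {
  d <- dim(arr)
  if (ax == 1L) {
    array(K %*% matrix(arr, d[1]), d)
  } else if (ax == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    p <- array(K %*% matrix(p, d[2]), c(d[2], d[1], d[3]))
    aperm(p, c(2, 1, 3))
  } else {
    m <- matrix(arr, d[1] * d[2], d[3])
    array(m %*% t(K), d)
  }
}
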