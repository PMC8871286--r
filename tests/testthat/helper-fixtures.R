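# Shared fixtures and independent oracles used across the suite.

# A small box-shaped liver mask (deterministic, no RNG).
box_mask <- function(shape = c(10, 10, 8), voxel = c(1, 1, 1)) {
  m <- array(0, shape)
  m[3:(shape[1] - 2), 3:(shape[2] - 2), 3:(shape[3] - 2)] <- 1
  vol_grid(m, voxel)
}

# Deterministic heterogeneous map on a box mask.
wavy_map <- function(shape = c(10, 10, 8), voxel = c(1, 1, 1),
                     base = 8, amp = 6) {
  mask <- box_mask(shape, voxel)
  idx <- which(array(TRUE, shape), arr.ind = TRUE)
  v <- base + amp * sin(idx[, 1] / 2) * cos(idx[, 2] / 3) +
    amp / 2 * sin(idx[, 3])
  v <- pmin(pmax(v, 0), 100)
  pdff_map(vol_grid(array(v, shape), voxel), mask)
}

# Brute-force LV% oracle: explicit triple loop over masked voxels.
lv_oracle <- function(map, th, ge = FALSE) {
  v <- map$map$values
  m <- map$mask$values
  d <- dim(v)
  n_mask <- 0
  n_above <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] == 1) {
      n_mask <- n_mask + 1
      hit <- if (ge) v[i, j, k] >= th else v[i, j, k] > th
      if (hit) n_above <- n_above + 1
    }
  }
  100 * n_above / n_mask
}

# Brute-force region-mean oracle.
mean_oracle <- function(map, region = NULL) {
  v <- map$map$values
  m <- map$mask$values
  r <- if (is.null(region)) array(1, dim(v)) else region$values
  d <- dim(v)
  s <- 0; n <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] == 1 && r[i, j, k] == 1) { s <- s + v[i, j, k]; n <- n + 1 }
  }
  s / n
}

# Independent connectivity check: iterated dilation from a single seed
# voxel (morphological region growing via array shifts), no shared code
# with the package's BFS.
is_connected6 <- function(arr) {
  arr <- arr == 1
  if (!any(arr)) return(FALSE)
  seed <- array(FALSE, dim(arr))
  seed[which(arr)[1]] <- TRUE
  shift1 <- function(a, ax, by) {
    d <- dim(a); out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  repeat {
    grown <- seed
    for (ax in 1:3) for (by in c(1, -1)) grown <- grown | shift1(seed, ax, by)
    grown <- grown & arr
    if (identical(grown, seed)) break
    seed <- grown
  }
  sum(seed) == sum(arr)
}

# Quick small-lattice generator configuration for pipeline tests.
quick_config <- function(n = 3, seed = 1, ...) {
  generator_config(n_per_arm = n, grid_shape = c(12, 12, 8),
                   voxel_size = c(2.5, 2.5, 2.5), voi_side = 10,
                   correlation_length = 5, seed = seed, ...)
}
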