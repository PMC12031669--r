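#' TOF sinogram container
#'
#' A flat vector indexed LOR-major over `(lor, tof_bin)`; see [flat_bin()].
#' The same container holds event counts `y` (nonnegative) or
#' lifetime-weighted sums `z` (real, possibly negative).
#'
#' @param values Numeric vector of length [n_bins()] (default zeros).
#' @param geom A [ring_geometry()].
#' @param role Free-text role tag (`"counts"` or `"tau_sum"`).
#' @return An object of class `tof_sinogram`.
#' @export
tof_sinogram <- function(geom, values = NULL, role = "counts") {
  m <- n_bins(geom)
  if (is.null(values)) values <- numeric(m)
  if (length(values) != m)
    stop("sinogram length ", length(values), " != n_lors * n_tof_bins = ", m)
  structure(list(values = as.numeric(values), n_lors = geom$n_lors,
                 n_tof_bins = geom$n_tof_bins, role = role),
            class = "tof_sinogram")
}

#' @export
print.tof_sinogram <- function(x, ...) {
  cat(sprintf("tof_sinogram [%s]: %d LORs x %d TOF bins, total %.6g\n",
              x$role, x$n_lors, x$n_tof_bins, sum(x$values)))
  invisible(x)
}

check_sino <- function(sino, geom) {
  if (inherits(sino, "tof_sinogram")) sino <- sino$values
  if (length(sino) != n_bins(geom))
    stop("sinogram/geometry shape mismatch")
  as.numeric(sino)
}

#' One row of the TOF system matrix
#'
#' The system matrix element `H[i, j]` is the probability (up to a common
#' geometric constant) that an annihilation in voxel `j` is detected in flat
#' TOF bin `i`: the Siddon intersection length of the LOR chord with the
#' voxel times the Gaussian TOF kernel integrated over the bin, evaluated at
#' the voxel's signed position along the LOR.
#'
#' @param lor 1-based LOR index.
#' @param tof_bin Signed TOF bin index (0 = central).
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()].
#' @return List with 1-based voxel indices `vox` (into the flattened image)
#'   and weights `w`; empty when the LOR misses the grid.
#' @export
system_row <- function(lor, tof_bin, geom, grid) {
  stopifnot(lor >= 1, lor <= geom$n_lors)
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  if (abs(tof_bin) > k0) stop("TOF bin outside sinogram range")
  a <- geom$lor_a[lor]; b <- geom$lor_b[lor]
  tr <- cpp_trace(geom$crystal_x[a], geom$crystal_y[a],
                  geom$crystal_x[b], geom$crystal_y[b],
                  grid$nx, grid$ny, grid$spacing)
  if (length(tr$vox) == 0L) return(list(vox = integer(0), w = numeric(0)))
  sc <- tof_bin * geom$s_bin
  if (geom$sigma_s > 0) {
    kern <- pnorm((sc + geom$s_bin / 2 - tr$s) / geom$sigma_s) -
            pnorm((sc - geom$s_bin / 2 - tr$s) / geom$sigma_s)
  } else {
    kern <- as.numeric(tr$s >= sc - geom$s_bin / 2 &
                       tr$s < sc + geom$s_bin / 2)
  }
  list(vox = tr$vox + 1L, w = tr$len * kern)
}

#' TOF forward projection
#'
#' Applies the system matrix on the fly: `y_i = sum_j H[i,j] x_j`.
#'
#' @param img An [image_grid()] (or matrix/vector of matching size).
#' @param geom A [ring_geometry()].
#' @param grid The [image_grid()] defining the voxelisation (defaults to
#'   `img` when that is an `image_grid`).
#' @param subset,n_subsets Optional angular subset selection (round-robin on
#'   the LOR azimuthal index), used by OSEM.
#' @return A [tof_sinogram()] of expected counts.
#' @export
forward_project <- function(img, geom, grid = NULL, subset = NULL,
                            n_subsets = 1L) {
  if (inherits(img, "image_grid")) {
    if (is.null(grid)) grid <- img
    x <- as.numeric(img$values)
  } else {
    if (is.null(grid)) stop("`grid` required when `img` is not an image_grid")
    x <- as.numeric(img)
  }
  if (length(x) != grid$nx * grid$ny) stop("image/grid shape mismatch")
  act <- active_lors(geom, grid, subset, n_subsets)
  v <- cpp_forward(x, grid$nx, grid$ny, grid$spacing,
                   geom$crystal_x, geom$crystal_y,
                   geom$lor_a - 1L, geom$lor_b - 1L, act - 1L,
                   geom$n_tof_bins, geom$s_bin, geom$sigma_s)
  tof_sinogram(geom, v, role = "expected")
}

#' TOF backprojection (adjoint of [forward_project()])
#'
#' @param sino A [tof_sinogram()] (or numeric vector of matching length).
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()] defining the output voxelisation.
#' @param subset,n_subsets Optional angular subset selection.
#' @return An [image_grid()].
#' @export
back_project <- function(sino, geom, grid, subset = NULL, n_subsets = 1L) {
  v <- check_sino(sino, geom)
  act <- active_lors(geom, grid, subset, n_subsets)
  img <- cpp_backward(v, grid$nx, grid$ny, grid$spacing,
                      geom$crystal_x, geom$crystal_y,
                      geom$lor_a - 1L, geom$lor_b - 1L, act - 1L,
                      geom$n_tof_bins, geom$s_bin, geom$sigma_s)
  grid_with_values(grid, img, role = "backprojection")
}

#' Sensitivity image
#'
#' Backprojection of a unit sinogram, `s_j = sum_i H[i,j]`, over all LORs or
#' an angular subset; the normaliser of the multiplicative updates.
#'
#' @inheritParams back_project
#' @return An [image_grid()].
#' @export
sensitivity_image <- function(geom, grid, subset = NULL, n_subsets = 1L) {
  act <- active_lors(geom, grid, subset, n_subsets)
  img <- cpp_sensitivity(grid$nx, grid$ny, grid$spacing,
                         geom$crystal_x, geom$crystal_y,
                         geom$lor_a - 1L, geom$lor_b - 1L, act - 1L,
                         geom$n_tof_bins, geom$s_bin, geom$sigma_s)
  grid_with_values(grid, img, role = "sensitivity")
}

#' Dense system matrix (small problems only)
#'
#' Materialises `H` row by row via [system_row()]; intended as a test oracle
#' and for inspecting small geometries, not for reconstruction.
#'
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()].
#' @return A dense `n_bins(geom)` x `nx*ny` matrix.
#' @export
dense_system_matrix <- function(geom, grid) {
  m <- n_bins(geom); nv <- grid$nx * grid$ny
  if (m * nv > 5e7) stop("geometry too large for a dense system matrix")
  H <- matrix(0, m, nv)
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  for (lor in seq_len(geom$n_lors)) {
    for (k in -k0:k0) {
      row <- system_row(lor, k, geom, grid)
      if (length(row$vox))
        H[flat_bin(lor, k, geom) + 1L, row$vox] <- row$w
    }
  }
  H
}
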