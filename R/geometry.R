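#' 2D reconstruction image grid
#'
#' A square-pixel 2D voxel grid centred on the scanner axis. Values are held
#' in an `nx` x `ny` matrix; voxel `(ix, iy)` (1-based) has its centre at
#' `((ix - (nx+1)/2) * spacing, (iy - (ny+1)/2) * spacing)` mm.
#'
#' @param nx,ny Grid dimensions (voxels).
#' @param spacing Voxel size, mm.
#' @param values Optional `nx` x `ny` matrix of voxel values (default zeros).
#' @param role Free-text role tag (e.g. `"activity"`, `"lifetime"`).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(nx, ny = nx, spacing = 1, values = NULL,
                       role = "image") {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid dimensions must be positive")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a positive scalar (mm)")
  if (is.null(values)) values <- matrix(0, nx, ny)
  values <- as.matrix(values)
  if (!all(dim(values) == c(nx, ny)))
    stop("`values` must be an nx x ny matrix")
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(list(nx = nx, ny = ny, spacing = spacing, values = values,
                 role = role),
            class = "image_grid")
}

#' Replace the values of an image grid
#' @param grid An [image_grid()].
#' @param values New value matrix (or vector of length `nx*ny`).
#' @param role Optional new role tag.
#' @return A new `image_grid`.
#' @export
grid_with_values <- function(grid, values, role = grid$role) {
  image_grid(grid$nx, grid$ny, grid$spacing,
             matrix(values, grid$nx, grid$ny), role)
}

#' Voxel-centre coordinates of a grid
#' @param grid An [image_grid()].
#' @return List with vectors `x`, `y` (mm) and matrices `xx`, `yy`.
#' @export
grid_coords <- function(grid) {
  x <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$spacing
  y <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$spacing
  list(x = x, y = y,
       xx = matrix(x, grid$nx, grid$ny),
       yy = matrix(y, grid$nx, grid$ny, byrow = TRUE))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid [%s]: %d x %d voxels @ %.3g mm, range [%.4g, %.4g]\n",
              x$role, x$nx, x$ny, x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Single-ring TOF scanner geometry
#'
#' Defines the 2D ring of crystals, the line-of-response (LOR) enumeration,
#' and the TOF binning used by the projector. Crystals sit at equal angular
#' pitch on a circle; LORs are unordered crystal pairs `(a, b)`, `a < b`,
#' whose angular separation is at least `min_arc` crystal steps (grazing
#' pairs carry no field-of-view information). The signed TOF coordinate of
#' a LOR runs from its midpoint toward crystal `b`; TOF bin centres are
#' spaced `tof_bin_width` ns in the pair time difference, i.e.
#' `c * tof_bin_width / 2` mm along the LOR, with the central bin (the grid
#' has an odd number of bins) at zero.
#'
#' @param n_crystals Number of crystals (even, >= 8).
#' @param ring_diameter Ring diameter, mm.
#' @param tof_fwhm Coincidence timing resolution FWHM of the pair time
#'   difference, ns.
#' @param tof_bin_width TOF bin width, ns; default `tof_fwhm / 2.5`.
#' @param n_tof_bins Odd number of TOF bins; if `NULL`, chosen so the bins
#'   cover `fov_radius` plus 5.5 Gaussian sd of the TOF kernel.
#' @param min_arc Minimum crystal-index separation of a LOR; default
#'   `n_crystals / 8`.
#' @param fov_radius Radius (mm) of the supported field of view, used to
#'   size the TOF bin range; default `0.35 * ring_diameter / 2`.
#' @return An object of class `ring_geometry` with crystal coordinates,
#'   the LOR pair table and a pair-to-LOR lookup.
#' @export
ring_geometry <- function(n_crystals, ring_diameter, tof_fwhm,
                          tof_bin_width = tof_fwhm / 2.5,
                          n_tof_bins = NULL,
                          min_arc = n_crystals %/% 8,
                          fov_radius = 0.35 * ring_diameter / 2) {
  n_crystals <- as.integer(n_crystals)
  if (n_crystals < 8L || n_crystals %% 2L != 0L)
    stop("`n_crystals` must be an even integer >= 8")
  if (ring_diameter <= 0) stop("`ring_diameter` must be positive (mm)")
  if (tof_fwhm < 0) stop("`tof_fwhm` must be nonnegative (ns)")
  if (tof_bin_width <= 0) stop("`tof_bin_width` must be positive (ns)")
  R <- ring_diameter / 2
  sigma_s <- .c_mm_ns * (tof_fwhm / 2.35482) / 2   # TOF kernel sd, mm
  s_bin <- .c_mm_ns * tof_bin_width / 2            # bin extent along LOR, mm
  if (is.null(n_tof_bins)) {
    half <- ceiling((fov_radius + 5.5 * sigma_s) / s_bin)
    n_tof_bins <- 2L * as.integer(half) + 1L
  }
  n_tof_bins <- as.integer(n_tof_bins)
  if (n_tof_bins < 1L || n_tof_bins %% 2L != 1L)
    stop("`n_tof_bins` must be a positive odd integer")
  ang <- 2 * pi * (seq_len(n_crystals) - 1) / n_crystals
  crx <- R * cos(ang); cry <- R * sin(ang)
  pairs <- which(upper.tri(matrix(0, n_crystals, n_crystals)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]              # 1-based, a < b
  arc <- pmin((b - a) %% n_crystals, (a - b) %% n_crystals)
  keep <- arc >= min_arc
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  n_lors <- length(a)
  lookup <- matrix(NA_integer_, n_crystals, n_crystals)
  lookup[cbind(a, b)] <- seq_len(n_lors)
  lookup[cbind(b, a)] <- seq_len(n_lors)
  # distance of each LOR chord from the ring centre
  mx <- (crx[a] + crx[b]) / 2; my <- (cry[a] + cry[b]) / 2
  d_centre <- sqrt(mx^2 + my^2)
  # azimuthal angle index used for round-robin subset partitioning
  angle_idx <- (a + b - 2L) %% n_crystals
  structure(list(
    n_crystals = n_crystals, ring_diameter = ring_diameter, R = R,
    tof_fwhm = tof_fwhm, tof_bin_width = tof_bin_width,
    n_tof_bins = n_tof_bins, min_arc = as.integer(min_arc),
    fov_radius = fov_radius,
    sigma_s = sigma_s, s_bin = s_bin,
    crystal_x = crx, crystal_y = cry,
    lor_a = a, lor_b = b, n_lors = n_lors,
    lor_lookup = lookup, lor_d_centre = d_centre,
    lor_angle_idx = angle_idx
  ), class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(paste0("ring_geometry: %d crystals, diameter %.0f mm, ",
                     "%d LORs, %d TOF bins (%.0f ps, kernel sd %.1f mm)\n"),
              x$n_crystals, x$ring_diameter, x$n_lors, x$n_tof_bins,
              1000 * x$tof_bin_width, x$sigma_s))
  invisible(x)
}

#' Number of flat TOF sinogram bins of a geometry
#' @param geom A [ring_geometry()].
#' @return `n_lors * n_tof_bins`.
#' @export
n_bins <- function(geom) geom$n_lors * geom$n_tof_bins

#' Flat sinogram bin index
#'
#' Flat bins are LOR-major and 0-based:
#' `bin = (lor - 1) * n_tof_bins + tof_bin + (n_tof_bins - 1)/2`,
#' with `tof_bin` the signed bin index (0 = central bin).
#'
#' @param lor 1-based LOR index.
#' @param tof_bin Signed TOF bin index.
#' @param geom A [ring_geometry()].
#' @return 0-based flat bin index.
#' @export
flat_bin <- function(lor, tof_bin, geom) {
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  if (any(abs(tof_bin) > k0)) stop("TOF bin outside sinogram range")
  (lor - 1L) * geom$n_tof_bins + tof_bin + k0
}

# LOR indices whose chord intersects the image grid circumcircle (others
# have identically empty system-matrix rows and are skipped by projections)
active_lors <- function(geom, grid, subset = NULL, n_subsets = 1L) {
  r_grid <- sqrt(2) / 2 * max(grid$nx, grid$ny) * grid$spacing
  act <- which(geom$lor_d_centre <= r_grid)
  if (!is.null(subset)) {
    act <- act[geom$lor_angle_idx[act] %% n_subsets == (subset - 1L)]
  }
  act
}
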