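#' Direct TOF-backprojection images
#'
#' The baseline lifetime pipeline forms its component images by a single
#' application of the transposed TOF system matrix to the data — no
#' iteration, no sensitivity division: `x_d = H'y`, `w_d = H'z`,
#' `x0_d = H'y0`.
#'
#' @param y,z Counts and tau-sum [tof_sinogram()]s (or numeric vectors).
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()].
#' @param y0 Optional doubles counts sinogram.
#' @return List of [image_grid()]s `x_d`, `w_d` and (when `y0` given)
#'   `x0_d`.
#' @export
tofbp_images <- function(y, z, geom, grid, y0 = NULL) {
  out <- list(x_d = back_project(y, geom, grid),
              w_d = back_project(z, geom, grid))
  if (!is.null(y0)) out$x0_d <- back_project(y0, geom, grid)
  out
}

#' Direct TOF-backprojection lifetime reconstruction
#'
#' Builds `y` and `z` from the gated events, backprojects them (and the
#' doubles data) with [tofbp_images()], and combines the three images with
#' the same randoms-corrected ratio and masking as the iterative pipeline.
#' The ratio structure makes the lifetime image invariant to any common
#' scaling of the backprojected images.
#'
#' @inheritParams reconstruct_simple
#' @return A `lifetime_result` (see [reconstruct_simple()]) with
#'   `method = "tofbp"`.
#' @export
reconstruct_tofbp <- function(events, geom, grid, cfg = recon_config(),
                              doubles = NULL, background_roi = NULL) {
  gated <- gate_and_bin(events, cfg$windows)
  sino <- build_z(gated$recon_events, geom)
  gamma <- cfg$gamma
  if (cfg$gamma_mode == "from_counts") {
    if (is.null(doubles))
      stop("`doubles` required for gamma_mode = 'from_counts'")
    n1 <- estimate_type1_in_recon_window(gated$correction_count, cfg$windows)
    gamma <- estimate_gamma(n1, doubles$n_doubles)
  }
  imgs <- tofbp_images(sino$y, sino$z, geom, grid,
                       y0 = if (gamma > 0) doubles$y0 else NULL)
  x0 <- NULL
  if (gamma > 0) {
    # backprojection is linear, so rescale to the doubles count like the
    # iterative path does
    x0 <- grid_with_values(
      imgs$x0_d,
      imgs$x0_d$values * doubles$n_doubles / max(sum(doubles$y0$values), 1),
      role = "activity_doubles")
  }
  res <- form_lifetime_image(imgs$w_d, imgs$x_d, x0, gamma, cfg$windows,
                             cfg$mu_hat, cfg, background_roi)
  structure(list(m = res$m, mask = res$mask, x_triple = imgs$x_d,
                 w_tilde = imgs$w_d, x0 = x0, gamma = gamma,
                 mu_hat = cfg$mu_hat,
                 correction_count = gated$correction_count,
                 n_events = nrow(gated$recon_events), cfg = cfg,
                 method = "tofbp"),
            class = "lifetime_result")
}
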