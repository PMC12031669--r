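#' Reconstruction configuration
#'
#' @param n_iterations Number of full (OS)EM iterations.
#' @param n_subsets Number of angular subsets (1 = plain MLEM).
#' @param windows A [time_windows()].
#' @param gamma_mode `"from_counts"` (estimate the type I randoms fraction
#'   from the correction-window count) or `"fixed"`.
#' @param gamma Fixed type I randoms fraction (used when
#'   `gamma_mode = "fixed"`; 0 disables the correction).
#' @param epsilon Small positive guard for divisions and the lower clamp of
#'   the lifetime-weighted image.
#' @param clamp_negative Clamp the lifetime-weighted image at `epsilon` from
#'   below after each update (`TRUE`, default) or zero out negative values
#'   (`FALSE`).
#' @param mask_fraction Activity fraction of the background level below
#'   which lifetime voxels are masked out of the display image.
#' @param mu_hat Scanner timing offset subtracted at image formation, ns.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 2, n_subsets = 3,
                         windows = time_windows(),
                         gamma_mode = c("from_counts", "fixed"), gamma = 0,
                         epsilon = 1e-10, clamp_negative = TRUE,
                         mask_fraction = 0.5, mu_hat = 0) {
  gamma_mode <- match.arg(gamma_mode)
  if (n_iterations < 1) stop("`n_iterations` must be >= 1")
  if (n_subsets < 1) stop("`n_subsets` must be >= 1")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (mask_fraction < 0 || mask_fraction > 1)
    stop("`mask_fraction` must be in [0, 1]")
  if (gamma < 0) stop("`gamma` must be nonnegative")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), windows = windows,
                 gamma_mode = gamma_mode, gamma = gamma, epsilon = epsilon,
                 clamp_negative = clamp_negative,
                 mask_fraction = mask_fraction, mu_hat = mu_hat),
            class = "recon_config")
}

#' Build count and lifetime-weighted sinograms from list-mode events
#'
#' Accumulates, per flat TOF sinogram bin, the event count `y_i` and the sum
#' of lifetime measurements `z_i = sum_k tau_k` over the events detected in
#' that bin. `sum(z)` equals `sum(tau)` exactly.
#'
#' @param events A data.frame with columns `lor`, `tof_bin`, `tau`, gated to
#'   the reconstruction window.
#' @param geom A [ring_geometry()].
#' @return List with [tof_sinogram()]s `y` (counts) and `z` (tau sums).
#' @export
build_z <- function(events, geom) {
  m <- n_bins(geom)
  if (nrow(events) == 0L)
    return(list(y = tof_sinogram(geom, role = "counts"),
                z = tof_sinogram(geom, role = "tau_sum")))
  fb <- flat_bin(events$lor, events$tof_bin, geom)
  if (any(fb < 0L | fb >= m)) stop("event bin out of sinogram range")
  y <- tabulate(fb + 1L, m)
  z <- numeric(m)
  acc <- rowsum(events$tau, fb)
  z[as.integer(rownames(acc)) + 1L] <- acc[, 1]
  list(y = tof_sinogram(geom, y, role = "counts"),
       z = tof_sinogram(geom, z, role = "tau_sum"))
}

# uniform positive start image: 1 inside the inscribed FOV circle, 0 outside
init_image <- function(grid) {
  co <- grid_coords(grid)
  r <- min(grid$nx, grid$ny) * grid$spacing / 2
  grid_with_values(grid, as.numeric(co$xx^2 + co$yy^2 <= r^2),
                   role = "activity")
}

# one multiplicative update of `img` against data sinogram `d` over a subset
mult_update <- function(img, d, geom, grid, sens, subset, n_subsets,
                        epsilon) {
  proj <- forward_project(img, geom, grid, subset, n_subsets)$values
  ratio <- ifelse(proj > epsilon, d / proj, 0)
  bp <- back_project(ratio, geom, grid, subset, n_subsets)$values
  s <- sens$values
  upd <- ifelse(s > 0, img$values * bp / s, 0)
  grid_with_values(img, upd, role = img$role)
}

#' MLEM / OSEM activity reconstruction
#'
#' Standard multiplicative expectation-maximisation updates
#' `x <- x / s * H'(y / Hx)` with the sensitivity image `s = H'1`,
#' optionally ordered-subset accelerated over round-robin angular subsets.
#' Initialised uniform inside the field-of-view circle.
#'
#' @param y A counts [tof_sinogram()] (or numeric vector).
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()] defining the reconstruction voxels.
#' @param cfg A [recon_config()].
#' @param x0 Optional starting [image_grid()].
#' @return An [image_grid()] activity estimate (nonnegative).
#' @export
mlem_activity <- function(y, geom, grid, cfg = recon_config(), x0 = NULL) {
  yv <- check_sino(y, geom)
  if (any(yv < 0)) stop("count sinogram must be nonnegative")
  ns <- cfg$n_subsets
  sens <- lapply(seq_len(ns), function(s)
    sensitivity_image(geom, grid, s, ns))
  x <- if (is.null(x0)) init_image(grid) else x0
  for (it in seq_len(cfg$n_iterations)) {
    for (s in seq_len(ns)) {
      x <- mult_update(x, yv, geom, grid, sens[[s]], s, ns, cfg$epsilon)
    }
  }
  x$role <- "activity"
  x
}

#' One time-weighted update of the lifetime-weighted image
#'
#' The binned form of the time-weighted MLEM update,
#' `w <- w / s * H'(z / Hw)`, where `z` holds per-bin lifetime sums. This
#' equals the list-mode update (weights `tau_k` per event) by construction
#' of `z`. After the update, values are clamped at `epsilon` from below
#' (or negatives zeroed, per `cfg$clamp_negative`), keeping the
#' multiplicative update defined when a few `z` entries are negative.
#'
#' @param w Current lifetime-weighted [image_grid()] (positive).
#' @param z A tau-sum [tof_sinogram()] (or numeric vector).
#' @param geom A [ring_geometry()].
#' @param cfg A [recon_config()].
#' @param subset,n_subsets Optional subset selection (default full MLEM).
#' @param sens Optional precomputed sensitivity [image_grid()] for the
#'   subset.
#' @return Updated [image_grid()].
#' @export
update_w <- function(w, z, geom, cfg = recon_config(), subset = NULL,
                     n_subsets = 1L, sens = NULL) {
  zv <- check_sino(z, geom)
  grid <- w
  if (is.null(sens)) sens <- sensitivity_image(geom, grid, subset, n_subsets)
  proj <- forward_project(w, geom, grid, subset, n_subsets)$values
  ratio <- ifelse(proj > cfg$epsilon, zv / proj, 0)
  bp <- back_project(ratio, geom, grid, subset, n_subsets)$values
  s <- sens$values
  upd <- ifelse(s > 0, w$values * bp / s, 0)
  if (cfg$clamp_negative) {
    upd[upd < cfg$epsilon & s > 0] <- cfg$epsilon
  } else {
    upd[upd < 0] <- 0
  }
  grid_with_values(w, upd, role = "lifetime_weighted")
}

#' List-mode time-weighted update
#'
#' The list-mode form of the time-weighted update: every event contributes
#' its own lifetime measurement as a weight,
#' `w_j <- w_j / s_j * sum_k H[i_k, j] tau_k / (H w)_{i_k}`,
#' accumulated row by row via [system_row()]. Mathematically identical to
#' the binned [update_w()] (events sharing a bin share a system-matrix
#' row); kept as an independent cross-check path and for small problems.
#'
#' @param w Current lifetime-weighted [image_grid()].
#' @param events Gated events (`lor`, `tof_bin`, `tau`).
#' @param geom A [ring_geometry()].
#' @param cfg A [recon_config()].
#' @return Updated [image_grid()].
#' @export
update_w_listmode <- function(w, events, geom, cfg = recon_config()) {
  grid <- w
  sens <- sensitivity_image(geom, grid)$values
  proj <- forward_project(w, geom, grid)$values
  acc <- numeric(grid$nx * grid$ny)
  for (k in seq_len(nrow(events))) {
    i <- flat_bin(events$lor[k], events$tof_bin[k], geom) + 1L
    if (proj[i] <= cfg$epsilon) next
    row <- system_row(events$lor[k], events$tof_bin[k], geom, grid)
    acc[row$vox] <- acc[row$vox] + row$w * events$tau[k] / proj[i]
  }
  upd <- ifelse(sens > 0, as.numeric(w$values) * acc / sens, 0)
  if (cfg$clamp_negative) upd[upd < cfg$epsilon & sens > 0] <- cfg$epsilon
  else upd[upd < 0] <- 0
  grid_with_values(w, upd, role = "lifetime_weighted")
}

#' Time-weighted (OS)EM reconstruction of the lifetime-weighted image
#'
#' Runs [update_w()] for `cfg$n_iterations` full iterations over
#' `cfg$n_subsets` angular subsets, from a uniform positive start.
#'
#' @inheritParams mlem_activity
#' @param z A tau-sum [tof_sinogram()].
#' @param w0 Optional starting image.
#' @return An [image_grid()] estimate of `w = x * m`.
#' @export
tw_mlem <- function(z, geom, grid, cfg = recon_config(), w0 = NULL) {
  ns <- cfg$n_subsets
  sens <- lapply(seq_len(ns), function(s)
    sensitivity_image(geom, grid, s, ns))
  w <- if (is.null(w0)) init_image(grid) else w0
  for (it in seq_len(cfg$n_iterations)) {
    for (s in seq_len(ns)) {
      w <- update_w(w, z, geom, cfg, s, ns, sens[[s]])
    }
  }
  w
}

#' Type I randoms fraction
#'
#' `gamma = (# type I randoms in the reconstruction window) / (# doubles)`.
#'
#' @param n_type1 Estimated number of type I randoms (see
#'   [estimate_type1_in_recon_window()]).
#' @param n_doubles Total number of double coincidences.
#' @return The fraction `gamma`.
#' @export
estimate_gamma <- function(n_type1, n_doubles) {
  if (n_doubles <= 0) stop("`n_doubles` must be positive")
  n_type1 / n_doubles
}

#' Estimate type I randoms in the reconstruction window
#'
#' Lifetime measurements of type I randoms are uniformly distributed, so
#' the count in the shifted correction window scales to the reconstruction
#' window by the ratio of window widths:
#' `count * (t_r2 - t_r1) / (t_c2 - t_c1)`.
#'
#' @param correction_count Events counted in the correction window.
#' @param windows A [time_windows()].
#' @return Estimated type I randoms count in the reconstruction window.
#' @export
estimate_type1_in_recon_window <- function(correction_count, windows) {
  wc <- windows$t_c2 - windows$t_c1
  if (wc <= 0) stop("correction window has zero width")
  correction_count * (windows$t_r2 - windows$t_r1) / wc
}

#' Form the lifetime image from component reconstructions
#'
#' Combines the type-I-included lifetime-weighted image `w_tilde`, the
#' type-I-included triple-activity image `x_tilde` and the doubles activity
#' image `x0` voxel-wise:
#' `m = (w_tilde - mid * gamma * x0) / (x_tilde - gamma * x0) - mu_hat`,
#' where `mid = (t_r1 + t_r2)/2` is the mean lifetime measurement of the
#' uniformly distributed type I randoms inside the reconstruction window.
#' A display mask keeps voxels whose activity is at least `mask_fraction`
#' of the mean background activity; the lifetime is set to zero outside.
#'
#' @param w_tilde,x_tilde,x0 Co-registered [image_grid()]s. `x0` may be
#'   `NULL` when `gamma = 0`.
#' @param gamma Type I randoms fraction.
#' @param windows A [time_windows()].
#' @param mu_hat Timing offset to subtract, ns.
#' @param cfg A [recon_config()] (supplies `epsilon` and `mask_fraction`).
#' @param background_roi Logical matrix selecting the background reference
#'   region of `x_tilde` used to set the mask level; when `NULL`, the mask
#'   level is `mask_fraction * mean positive activity`.
#' @return List with `m` (lifetime [image_grid()], ns) and `mask`
#'   (0/1 [image_grid()]).
#' @export
form_lifetime_image <- function(w_tilde, x_tilde, x0 = NULL, gamma = 0,
                                windows = time_windows(), mu_hat = 0,
                                cfg = recon_config(),
                                background_roi = NULL) {
  wv <- w_tilde$values; xv <- x_tilde$values
  if (gamma > 0) {
    if (is.null(x0))
      stop("`x0` is required when `gamma` > 0")
    x0v <- x0$values
    # match the doubles-image scale to the triples activity image so that
    # gamma * x0 carries the estimated type I counts (MLEM preserves counts)
    mid <- (windows$t_r1 + windows$t_r2) / 2
    num <- wv - mid * gamma * x0v
    den <- xv - gamma * x0v
  } else {
    num <- wv
    den <- xv
  }
  m <- ifelse(abs(den) > cfg$epsilon, num / den, 0) - mu_hat
  if (is.null(background_roi)) {
    level <- cfg$mask_fraction * mean(xv[xv > 0])
  } else {
    if (!any(background_roi)) stop("empty background ROI for the mask")
    level <- cfg$mask_fraction * mean(xv[background_roi])
  }
  mask <- xv >= level
  m[!mask] <- 0
  list(m = grid_with_values(w_tilde, m, role = "lifetime"),
       mask = grid_with_values(w_tilde, mask * 1, role = "mask"))
}

#' SIMPLE positron-lifetime reconstruction
#'
#' Full pipeline: build the count sinogram `y` and lifetime-weighted
#' sinogram `z` from the gated events; reconstruct the type-I-included
#' activity `x_tilde` from `y` and the lifetime-weighted image `w_tilde`
#' from `z` (time-weighted OSEM); reconstruct the doubles activity `x0`;
#' estimate the type I randoms fraction `gamma` from the correction-window
#' count; and combine via [form_lifetime_image()]. The computational cost
#' is that of reconstructing two standard activity images (plus the cheap
#' doubles reconstruction when randoms are corrected).
#'
#' @param events Data.frame of PLI events (`lor`, `tof_bin`, `tau`), not
#'   yet gated: [gate_and_bin()] is applied with `cfg$windows`.
#' @param geom A [ring_geometry()].
#' @param grid An [image_grid()].
#' @param cfg A [recon_config()].
#' @param doubles Optional list with `y0` (a counts [tof_sinogram()] of
#'   double coincidences) and `n_doubles`; required unless the randoms
#'   correction is disabled (`gamma_mode = "fixed"`, `gamma = 0`).
#' @param background_roi Optional logical matrix for the mask level (see
#'   [form_lifetime_image()]).
#' @return An object of class `lifetime_result`: list with images `m`,
#'   `mask`, `x_triple`, `w_tilde`, `x0`, scalars `gamma`, `mu_hat`,
#'   `correction_count`, `n_events`, and the `cfg` used.
#' @export
reconstruct_simple <- function(events, geom, grid, cfg = recon_config(),
                               doubles = NULL, background_roi = NULL) {
  gated <- gate_and_bin(events, cfg$windows)
  sino <- build_z(gated$recon_events, geom)
  x_tilde <- mlem_activity(sino$y, geom, grid, cfg)
  w_tilde <- tw_mlem(sino$z, geom, grid, cfg)
  gamma <- cfg$gamma
  x0 <- NULL
  if (cfg$gamma_mode == "from_counts") {
    if (is.null(doubles))
      stop("`doubles` (y0 sinogram and n_doubles) required for ",
           "gamma_mode = 'from_counts'")
    n1 <- estimate_type1_in_recon_window(gated$correction_count, cfg$windows)
    gamma <- estimate_gamma(n1, doubles$n_doubles)
  }
  if (gamma > 0) {
    if (is.null(doubles))
      stop("`doubles` required when gamma > 0")
    x0 <- mlem_activity(doubles$y0, geom, grid, cfg)
    # bring x0 to the triples count scale: gamma * x0 must carry the
    # estimated type I counts, and gamma is defined against n_doubles
    x0 <- grid_with_values(
      x0, x0$values * doubles$n_doubles / max(sum(doubles$y0$values), 1),
      role = "activity_doubles")
  }
  res <- form_lifetime_image(w_tilde, x_tilde, x0, gamma, cfg$windows,
                             cfg$mu_hat, cfg, background_roi)
  structure(list(m = res$m, mask = res$mask, x_triple = x_tilde,
                 w_tilde = w_tilde, x0 = x0, gamma = gamma,
                 mu_hat = cfg$mu_hat,
                 correction_count = gated$correction_count,
                 n_events = nrow(gated$recon_events), cfg = cfg,
                 method = "simple"),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("lifetime_result [%s]: %d events, gamma = %.4g, mu = %.3f ns\n",
              x$method, x$n_events, x$gamma, x$mu_hat))
  inside <- x$mask$values > 0
  if (any(inside))
    cat(sprintf("  masked lifetime range: [%.3f, %.3f] ns over %d voxels\n",
                min(x$m$values[inside]), max(x$m$values[inside]),
                sum(inside)))
  invisible(x)
}
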