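# Synthetic list-mode event generation.
#
# Photon pairs are emitted back-to-back along a uniformly random in-plane
# angle; no acollinearity, positron range, scatter or attenuation. Detection
# snaps each photon to the nearest crystal centre; the annihilation point is
# then projected onto the recorded crystal-pair chord, so that the geometric
# event model (times, TOF coordinate) is exactly self-consistent with the
# travel-time correction and the chord-based projector.

# sample n emission positions with per-voxel weight `w` (matrix), uniform
# jitter within the voxel; returns positions and 1-based flat voxel index
sample_emission <- function(grid, w, n) {
  p <- as.numeric(w)
  if (sum(p) <= 0) stop("phantom has no activity")
  vox <- sample.int(length(p), n, replace = TRUE, prob = p)
  ix <- (vox - 1L) %% grid$nx
  iy <- (vox - 1L) %/% grid$nx
  x <- (ix + runif(n) - grid$nx / 2) * grid$spacing
  y <- (iy + runif(n) - grid$ny / 2) * grid$spacing
  list(x = x, y = y, vox = vox)
}

# nearest crystal id (1-based) for hit angles
crystal_at <- function(geom, ang) {
  idx <- round(ang / (2 * pi / geom$n_crystals)) %% geom$n_crystals
  as.integer(idx) + 1L
}

# back-to-back pair emission from points (px, py): returns ordered crystal
# pair (a < b), the chord-projected emission point (qx, qy) and its signed
# position s along the chord (positive toward b), plus chord length
emit_pair <- function(geom, px, py) {
  n <- length(px)
  th <- runif(n, 0, pi)
  dx <- cos(th); dy <- sin(th)
  pd <- px * dx + py * dy
  disc <- sqrt(pmax(pd^2 + geom$R^2 - (px^2 + py^2), 0))
  t1 <- -pd + disc; t2 <- -pd - disc
  c1 <- crystal_at(geom, atan2(py + t1 * dy, px + t1 * dx) %% (2 * pi))
  c2 <- crystal_at(geom, atan2(py + t2 * dy, px + t2 * dx) %% (2 * pi))
  a <- pmin(c1, c2); b <- pmax(c1, c2)
  ax <- geom$crystal_x[a]; ay <- geom$crystal_y[a]
  bx <- geom$crystal_x[b]; by <- geom$crystal_y[b]
  ux <- bx - ax; uy <- by - ay
  L <- sqrt(ux^2 + uy^2)
  ux <- ux / L; uy <- uy / L
  # distance of p from crystal a along the chord, and projected point
  t_along <- (px - ax) * ux + (py - ay) * uy
  qx <- ax + t_along * ux; qy <- ay + t_along * uy
  list(a = a, b = b, s = t_along - L / 2, L = L, qx = qx, qy = qy,
       degenerate = c1 == c2)
}

# TOF-bin a signed chord coordinate s (mm) after pair timing blur;
# returns signed bin k or NA when outside the sinogram TOF range
tof_bin_of <- function(geom, s, blur = TRUE) {
  dt <- 2 * s / .c_mm_ns
  if (blur && geom$tof_fwhm > 0)
    dt <- dt + rnorm(length(s), 0, geom$tof_fwhm / 2.35482)
  k <- as.integer(round(dt / geom$tof_bin_width))
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  k[abs(k) > k0] <- NA_integer_
  k
}

#' Simulate list-mode triple coincidences
#'
#' Generates PLI events from a phantom: true triples by sampling an emission
#' voxel proportional to activity times prompt-gamma efficiency, a uniform
#' in-plane pair angle, the exact TOF coordinate (blurred by the pair timing
#' resolution and binned), and a lifetime measurement drawn from the local
#' decay model; plus type I, II and III random triples at the requested
#' randoms-to-trues ratios (defined within the reconstruction window of
#' `windows`). Type I randoms pair a real annihilation photon pair with an
#' unrelated prompt gamma, so their spatial/TOF process follows the activity
#' while their lifetime measurement is uniform over the retention range.
#' Types II and III replace one or both annihilation photons by photons
#' from independent decays (an independent-draw approximation of pile-up in
#' a full photon-transport simulation). Events whose lifetime measurement
#' falls outside `retention` are dropped.
#'
#' @param phantom A [pli_phantom()].
#' @param geom A [ring_geometry()].
#' @param timing A [timing_model()] for the lifetime measurement.
#' @param n_true Number of true triples to generate (before retention).
#' @param randoms Numeric length-3, randoms-to-trues ratios for types
#'   I, II, III measured in the reconstruction window; default none.
#' @param windows A [time_windows()] defining the reconstruction window the
#'   ratios refer to.
#' @param retention Lifetime retention range, ns (events outside dropped).
#' @param pair_window Maximum 511-keV pair time difference, ns (used for
#'   the random-coincidence timing of types II/III).
#' @param seed Optional integer master seed.
#' @return A data.frame with columns `lor` (1-based LOR index), `tof_bin`
#'   (signed TOF bin), `tau` (ns), `truth_class`
#'   (`"true"`, `"I"`, `"II.a"`, `"II.b"`, `"III"`) and `voxel` (1-based
#'   emission voxel of the annihilation pair; NA for type III).
#' @export
simulate_triples <- function(phantom, geom, timing = timing_model(),
                             n_true, randoms = c(0, 0, 0),
                             windows = time_windows(),
                             retention = c(-20, 20), pair_window = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_true <- as.integer(n_true)
  if (n_true < 1L) stop("`n_true` must be >= 1")
  randoms <- as.numeric(randoms)
  if (length(randoms) != 3L || any(randoms < 0))
    stop("`randoms` must be 3 nonnegative ratios (type I, II, III)")
  grid <- phantom$grid
  l_ret <- diff(retention)
  l_rec <- windows$t_r2 - windows$t_r1

  make_true <- function(n) {
    em <- sample_emission(grid, phantom$activity * phantom$pg_efficiency, n)
    pr <- emit_pair(geom, em$x, em$y)
    lor <- geom$lor_lookup[cbind(pr$a, pr$b)]
    k <- tof_bin_of(geom, pr$s)
    tau <- sample_region_lifetime(phantom, em$vox, timing)
    ok <- !pr$degenerate & !is.na(lor) & !is.na(k) &
      tau >= retention[1] & tau <= retention[2]
    data.frame(lor = lor[ok], tof_bin = k[ok], tau = tau[ok],
               truth_class = rep("true", sum(ok)), voxel = em$vox[ok])
  }

  make_type1 <- function(n) {
    if (n < 1L) return(NULL)
    em <- sample_emission(grid, phantom$activity, n)
    pr <- emit_pair(geom, em$x, em$y)
    lor <- geom$lor_lookup[cbind(pr$a, pr$b)]
    k <- tof_bin_of(geom, pr$s)
    tau <- runif(n, retention[1], retention[2])
    ok <- !pr$degenerate & !is.na(lor) & !is.na(k)
    data.frame(lor = lor[ok], tof_bin = k[ok], tau = tau[ok],
               truth_class = rep("I", sum(ok)), voxel = em$vox[ok])
  }

  # one 511-keV photon of decay A is paired with a photon from decay B
  make_type23 <- function(n, type3 = FALSE) {
    if (n < 1L) return(NULL)
    emA <- sample_emission(grid, phantom$activity * phantom$pg_efficiency, n)
    emB <- sample_emission(grid, phantom$activity, n)
    # prompt gamma of decay A (decay at time 0)
    phi <- runif(n, 0, 2 * pi)
    cpg <- crystal_at(geom, phi)
    dpg <- sqrt((emA$x - geom$crystal_x[cpg])^2 +
                (emA$y - geom$crystal_y[cpg])^2)
    tpg <- dpg / .c_mm_ns
    if (type3) {
      # all three photons unrelated: first 511 at an arbitrary offset
      emC <- sample_emission(grid, phantom$activity, n)
      x1 <- emC$x; y1 <- emC$y
      t1e <- tpg + runif(n, retention[1], retention[2])
      vox_pair <- rep(NA_integer_, n)
    } else {
      x1 <- emA$x; y1 <- emA$y
      t1e <- sample_region_lifetime(phantom, emA$vox, timing_model(0, 0))
      vox_pair <- emA$vox
    }
    th1 <- runif(n, 0, 2 * pi)
    c1 <- crystal_at(geom, th1)
    d1 <- sqrt((x1 - geom$crystal_x[c1])^2 + (y1 - geom$crystal_y[c1])^2)
    t1 <- t1e + d1 / .c_mm_ns
    th2 <- runif(n, 0, 2 * pi)
    c2 <- crystal_at(geom, th2)
    t2 <- t1 + runif(n, -pair_window, pair_window)
    blur <- if (geom$tof_fwhm > 0) rnorm(n, 0, geom$tof_fwhm / 2.35482)
            else numeric(n)
    a <- pmin(c1, c2); b <- pmax(c1, c2)
    valid <- which(c1 != c2 & !is.na(geom$lor_lookup[cbind(a, b)]))
    if (length(valid) == 0L) return(NULL)
    ta <- ifelse(c1 <= c2, t1, t2)[valid]
    tb <- ifelse(c1 <= c2, t2, t1)[valid]
    cls <- (if (type3) rep("III", n) else
            ifelse(c1 <= c2, "II.a", "II.b"))[valid]
    a <- a[valid]; b <- b[valid]
    lor <- geom$lor_lookup[cbind(a, b)]
    k0 <- (geom$n_tof_bins - 1L) %/% 2L
    k <- as.integer(round((ta - tb + blur[valid]) / geom$tof_bin_width))
    k[abs(k) > k0] <- NA_integer_
    tau <- lifetime_from_triple(geom, a, b, cpg[valid], ta, tb, tpg[valid])
    ok <- !is.na(k) & tau >= retention[1] & tau <= retention[2]
    data.frame(lor = lor[ok], tof_bin = k[ok], tau = tau[ok],
               truth_class = cls[ok], voxel = vox_pair[valid][ok])
  }

  trues <- make_true(n_true)
  # ratios are defined against trues within the reconstruction window.
  # Type I lifetimes are uniform over retention, so the total count scales
  # analytically by the window-width ratio; types II/III have non-uniform
  # lifetime distributions, so a candidate pool is generated and thinned to
  # the target in-window count, preserving the spectrum shape.
  n1 <- rbinom(1L, n_true, min(1, randoms[1] * l_ret / l_rec))
  make_randoms_23 <- function(ratio, type3) {
    if (ratio <= 0) return(NULL)
    target <- rbinom(1L, n_true, min(1, ratio))
    if (target < 1L) return(NULL)
    pool <- make_type23(max(1000L, 8L * target), type3 = type3)
    if (is.null(pool) || nrow(pool) == 0L) return(NULL)
    n_in <- sum(pool$tau >= windows$t_r1 & pool$tau <= windows$t_r2)
    if (n_in == 0L) return(NULL)
    pool[runif(nrow(pool)) < min(1, target / n_in), , drop = FALSE]
  }
  out <- rbind(trues, make_type1(n1), make_randoms_23(randoms[2], FALSE),
               make_randoms_23(randoms[3], TRUE))
  rownames(out) <- NULL
  out
}

# lifetime measurement for emissions located in phantom voxels
sample_region_lifetime <- function(phantom, vox, timing) {
  lab <- phantom$labels[vox]
  tau <- numeric(length(vox))
  for (nm in names(phantom$regions)) {
    id <- phantom$region_ids[[nm]]
    sel <- lab == id
    if (any(sel))
      tau[sel] <- sample_lifetime(sum(sel), phantom$regions[[nm]]$model,
                                  timing)
  }
  tau
}

#' Simulate a double-coincidence sinogram
#'
#' Standard PET acquisition of annihilation pairs (no prompt gamma):
#' emission voxels follow the activity alone. Used to reconstruct the
#' total-activity image for type I randoms correction.
#'
#' @param phantom A [pli_phantom()].
#' @param geom A [ring_geometry()].
#' @param n Number of pairs.
#' @param seed Optional integer seed.
#' @return List with `y0` (a [tof_sinogram()] of counts) and `n_doubles`
#'   (pairs actually binned).
#' @export
simulate_doubles <- function(phantom, geom, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  em <- sample_emission(phantom$grid, phantom$activity, as.integer(n))
  pr <- emit_pair(geom, em$x, em$y)
  lor <- geom$lor_lookup[cbind(pr$a, pr$b)]
  k <- tof_bin_of(geom, pr$s)
  ok <- !pr$degenerate & !is.na(lor) & !is.na(k)
  fb <- flat_bin(lor[ok], k[ok], geom)
  y0 <- tof_sinogram(geom, tabulate(fb + 1L, n_bins(geom)), role = "counts")
  list(y0 = y0, n_doubles = sum(ok))
}

#' Simulate a raw singles stream
#'
#' Emits, for each decay, one prompt gamma at the decay time and a 511-keV
#' photon pair delayed by the sampled positron lifetime. Detection times are
#' flight times to the recorded crystal centres (from the chord-projected
#' annihilation point for the pair) plus optional per-single Gaussian jitter;
#' energies carry a Gaussian blur of fractional FWHM `energy_res` at 511 keV
#' scaled by `sqrt(E)`. Each single is detected independently with
#' probability `efficiency` (prompt gammas additionally by the phantom's
#' per-voxel prompt-gamma efficiency). The stream is globally time-sorted.
#'
#' @param phantom A [pli_phantom()].
#' @param geom A [ring_geometry()].
#' @param duration Scan duration, ns.
#' @param activity_bq Total object activity, Bq.
#' @param pg_line Prompt-gamma line energy, keV (1157 or 1275).
#' @param energy_res Fractional energy resolution (FWHM) at 511 keV;
#'   0 disables energy blur.
#' @param efficiency Per-single detection probability.
#' @param single_sigma Per-single detection-time jitter sd, ns; default
#'   derived from the geometry's pair timing resolution
#'   (`tof_fwhm / 2.355 / sqrt(2)`).
#' @param seed Optional integer seed.
#' @return A data.frame sorted by `time` with columns `time` (ns),
#'   `crystal` (1-based), `energy` (keV), `kind` (`"511"` or `"PG"`) and
#'   `decay_id`.
#' @export
simulate_singles <- function(phantom, geom, duration, activity_bq,
                             pg_line = 1157, energy_res = 0.13,
                             efficiency = 1,
                             single_sigma = geom$tof_fwhm / 2.35482 / sqrt(2),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration <= 0) stop("`duration` must be positive (ns)")
  n <- rpois(1L, activity_bq * 1e-9 * duration)
  if (n < 1L) {
    return(data.frame(time = numeric(0), crystal = integer(0),
                      energy = numeric(0), kind = character(0),
                      decay_id = integer(0)))
  }
  t_decay <- sort(runif(n, 0, duration))
  em <- sample_emission(phantom$grid, phantom$activity, n)
  tau <- sample_region_lifetime(phantom, em$vox, timing_model(0, 0))
  pr <- emit_pair(geom, em$x, em$y)
  # pair photons fly from the chord-projected point to the crystal centres
  t_ann <- t_decay + tau
  t_at_a <- t_ann + (pr$L / 2 + pr$s) / .c_mm_ns
  t_at_b <- t_ann + (pr$L / 2 - pr$s) / .c_mm_ns
  # prompt gamma from the same (projected) point, independent direction
  phi <- runif(n, 0, 2 * pi)
  cpg <- crystal_at(geom, phi)
  dpg <- sqrt((pr$qx - geom$crystal_x[cpg])^2 +
              (pr$qy - geom$crystal_y[cpg])^2)
  tpg <- t_decay + dpg / .c_mm_ns
  e_sigma <- function(e) {
    if (energy_res <= 0) return(rep(0, length(e)))
    energy_res * sqrt(511 * e) / 2.35482
  }
  blur_e <- function(e0, m) {
    if (energy_res <= 0) rep(e0, m) else rnorm(m, e0, e_sigma(e0))
  }
  jit <- function(m) if (single_sigma > 0) rnorm(m, 0, single_sigma) else 0
  singles <- rbind(
    data.frame(time = t_at_a + jit(n), crystal = pr$a,
               energy = blur_e(511, n), kind = "511",
               decay_id = seq_len(n),
               det = runif(n) <= efficiency, o = !pr$degenerate),
    data.frame(time = t_at_b + jit(n), crystal = pr$b,
               energy = blur_e(511, n), kind = "511",
               decay_id = seq_len(n),
               det = runif(n) <= efficiency, o = !pr$degenerate),
    data.frame(time = tpg + jit(n), crystal = cpg,
               energy = blur_e(pg_line, n), kind = "PG",
               decay_id = seq_len(n),
               det = runif(n) <= efficiency * phantom$pg_efficiency[em$vox],
               o = TRUE)
  )
  singles <- singles[singles$det & singles$o, c("time", "crystal", "energy",
                                                "kind", "decay_id")]
  singles <- singles[order(singles$time), ]
  rownames(singles) <- NULL
  # ground-truth sidecar (provenance): per-decay lifetime and emission voxel
  attr(singles, "decays") <- data.frame(decay_id = seq_len(n),
                                        t_decay = t_decay, tau = tau,
                                        voxel = em$vox)
  singles
}
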