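test_that("z and y sinograms accumulate counts and lifetime sums", {
  geom <- tiny_geom()
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  ev <- data.frame(lor = c(1, 1, 2), tof_bin = c(3 - k0, 3 - k0, 7 - k0),
                   tau = c(1.0, 0.5, 2.0))
  sz <- build_z(ev, geom)
  expect_equal(sz$z$values[4], 1.5)
  expect_equal(sz$z$values[geom$n_tof_bins + 8], 2.0)
  expect_equal(sz$y$values[4], 2)
  expect_equal(sz$y$values[geom$n_tof_bins + 8], 1)
  expect_equal(sum(sz$z$values), sum(ev$tau))
  expect_equal(sum(sz$y$values), nrow(ev))

  empty <- build_z(ev[0, ], geom)
  expect_equal(sum(abs(empty$z$values)), 0)
  expect_equal(sum(empty$y$values), 0)

  # brute-force accumulation oracle on random events
  set.seed(10)
  n <- 1e4
  ev2 <- data.frame(lor = sample.int(geom$n_lors, n, replace = TRUE),
                    tof_bin = sample(-k0:k0, n, replace = TRUE),
                    tau = rnorm(n, 1, 2))
  sz2 <- build_z(ev2, geom)
  zo <- numeric(n_bins(geom)); yo <- numeric(n_bins(geom))
  for (k in seq_len(n)) {
    i <- flat_bin(ev2$lor[k], ev2$tof_bin[k], geom) + 1L
    zo[i] <- zo[i] + ev2$tau[k]; yo[i] <- yo[i] + 1
  }
  expect_equal(sz2$z$values, zo, tolerance = 1e-12)
  expect_equal(sz2$y$values, yo)
})

test_that("MLEM preserves counts and concentrates a point source", {
  geom <- mid_geom()
  grid <- image_grid(16, 16, spacing = 5)
  x <- matrix(0, 16, 16); x[9, 9] <- 1
  y <- forward_project(grid_with_values(grid, x), geom)
  cfg <- recon_config(n_iterations = 20, n_subsets = 1,
                      gamma_mode = "fixed")
  xh <- mlem_activity(y, geom, grid, cfg)
  # count preservation after full iterations
  expect_equal(sum(forward_project(xh, geom)$values), sum(y$values),
               tolerance = 1e-6)
  # mass concentrates on the source neighbourhood
  frac <- sum(xh$values[8:10, 8:10]) / sum(xh$values)
  expect_gt(frac, 0.95)
})

test_that("noiseless data is a fixed point of the MLEM update", {
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  x_true <- grid_with_values(grid, phan$activity)
  y <- forward_project(x_true, geom)
  cfg <- recon_config(n_iterations = 1, n_subsets = 3,
                      gamma_mode = "fixed")
  xh <- mlem_activity(y, geom, grid, cfg, x0 = x_true)
  expect_lt(max(abs(xh$values - x_true$values)), 1e-8 * max(x_true$values))
})

test_that("time-weighted update matches its algebra, oracle and fixed point", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  set.seed(4)
  w <- grid_with_values(grid, matrix(runif(64, 0.5, 2), 8, 8))
  z <- runif(n_bins(geom), 0, 2)
  cfg <- recon_config(gamma_mode = "fixed")
  up <- update_w(w, z, geom, cfg)
  # dense-oracle evaluation of w/s * H'(z / Hw)
  H <- dense_system_matrix(geom, grid)
  proj <- as.numeric(H %*% as.numeric(w$values))
  ratio <- ifelse(proj > cfg$epsilon, z / proj, 0)
  s <- as.numeric(crossprod(H, rep(1, nrow(H))))
  want <- ifelse(s > 0, as.numeric(w$values) *
                 as.numeric(crossprod(H, ratio)) / s, 0)
  want[want < cfg$epsilon & s > 0] <- cfg$epsilon
  expect_lt(max(abs(as.numeric(up$values) - want)), 1e-10)

  # z = Hw exactly -> fixed point
  zfix <- forward_project(w, geom)$values
  upf <- update_w(w, zfix, geom, cfg)
  inside <- sensitivity_image(geom, grid)$values > 0
  expect_lt(max(abs(upf$values[inside] - w$values[inside])) /
            max(w$values), 1e-10)
})

test_that("binned and list-mode time-weighted updates agree", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  set.seed(5)
  n <- 500
  ev <- data.frame(lor = sample.int(geom$n_lors, n, replace = TRUE),
                   tof_bin = sample(-2:2, n, replace = TRUE),
                   tau = runif(n, -1, 15))
  sz <- build_z(ev, geom)
  w <- grid_with_values(grid, matrix(1, 8, 8))
  cfg <- recon_config(gamma_mode = "fixed")
  wb <- update_w(w, sz$z, geom, cfg)
  wl <- update_w_listmode(w, ev, geom, cfg)
  expect_lt(max(abs(wb$values - wl$values)), 1e-9)
})

test_that("constant lifetime measurements give a constant lifetime image", {
  # with all tau_k = c, z = c * y and the time-weighted trajectory is
  # exactly c times the MLEM trajectory, so m = c everywhere in the mask
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  ev <- simulate_triples(phan, geom, timing_model(0, 0), n_true = 5e4,
                         randoms = c(0, 0, 0), seed = 30)
  ev$tau <- 1.7
  cfg <- recon_config(n_iterations = 2, n_subsets = 3,
                      gamma_mode = "fixed")
  res <- reconstruct_simple(ev, geom, grid, cfg)
  inside <- res$mask$values > 0
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(res$m$values[inside] - 1.7)), 1e-6)
})

test_that("uniform-lifetime noiseless data reconstructs a constant image", {
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  m0 <- 1.0
  x_true <- grid_with_values(grid, phan$activity)
  y <- forward_project(x_true, geom)
  z <- tof_sinogram(geom, m0 * y$values, role = "tau_sum")
  cfg <- recon_config(n_iterations = 17, n_subsets = 3,
                      gamma_mode = "fixed")
  xh <- mlem_activity(y, geom, grid, cfg)
  wh <- tw_mlem(z, geom, grid, cfg)
  fl <- form_lifetime_image(wh, xh, cfg = cfg)
  co <- grid_coords(grid)
  interior <- co$xx^2 + co$yy^2 <= 18^2
  expect_lt(max(abs(fl$m$values[interior] - m0)), 0.01)
})

test_that("randoms scaling arithmetic follows the window-width ratio", {
  wins <- time_windows(c(-1, 15), c(-20, -5))
  expect_equal(estimate_type1_in_recon_window(4.1e6, wins),
               4.1e6 * 16 / 15)
  weq <- time_windows(c(-1, 15), c(-18, -2))
  expect_equal(estimate_type1_in_recon_window(123, weq), 123)
  expect_equal(estimate_type1_in_recon_window(0, wins), 0)
  expect_equal(estimate_gamma(100, 10000), 0.01)
  expect_equal(estimate_gamma(0, 5), 0)
  expect_error(estimate_gamma(1, 0), "positive")
})

test_that("correction-window estimate agrees with ground-truth type I count", {
  phan <- mid_phantom()
  geom <- mid_geom()
  wins <- time_windows()
  ev <- simulate_triples(phan, geom, timing_model(0.092, 0), n_true = 2e5,
                         randoms = c(0.049, 0, 0), windows = wins,
                         seed = 31)
  g <- gate_and_bin(ev, wins)
  est <- estimate_type1_in_recon_window(g$correction_count, wins)
  in_rec <- ev$tau >= wins$t_r1 & ev$tau <= wins$t_r2
  truth <- sum(ev$truth_class == "I" & in_rec)
  expect_lt(abs(est - truth), 3 * sqrt(truth))
})

test_that("lifetime image formation follows the corrected ratio formula", {
  grid <- image_grid(2, 2, 1)
  mk <- function(v) grid_with_values(grid, matrix(v, 2, 2))
  cfg <- recon_config(gamma_mode = "fixed", mask_fraction = 0)
  # gamma = 0, mu = 0: plain voxel-wise ratio
  fl0 <- form_lifetime_image(mk(3), mk(2), cfg = cfg)
  expect_equal(unique(as.numeric(fl0$m$values)), 1.5)
  # corrected hand case: (30 - 7*0.5*2) / (10 - 0.5*2) = 23/9
  fl <- form_lifetime_image(mk(30), mk(10), mk(2), gamma = 0.5,
                            windows = time_windows(c(-1, 15), c(-20, -5)),
                            cfg = cfg)
  expect_equal(unique(as.numeric(fl$m$values)), 23 / 9,
               tolerance = 1e-12)
  # mu subtraction applies at the end
  flmu <- form_lifetime_image(mk(3), mk(2), mu_hat = 0.25, cfg = cfg)
  expect_equal(unique(as.numeric(flmu$m$values)), 1.25)
  # mask: voxels below mask_fraction x background level are zeroed
  x <- mk(c(10, 10, 1, 10))
  w <- mk(c(5, 5, 5, 5))
  cfgm <- recon_config(gamma_mode = "fixed", mask_fraction = 0.5)
  bg <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  flm <- form_lifetime_image(w, x, cfg = cfgm, background_roi = bg)
  expect_equal(as.numeric(flm$mask$values), c(1, 1, 0, 1))
  expect_equal(as.numeric(flm$m$values)[3], 0)
})

test_that("lifetime image is invariant to prompt-gamma efficiency scaling", {
  # the PG-sensitivity matrix Q scales y and z identically, so it cancels
  # in the ratio image: reconstruct noiseless data with and without a
  # spatially varying efficiency
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  co <- grid_coords(grid)
  q <- 1 - 0.5 * (co$xx > 0)         # efficiency halved on one side
  m_true <- 0.9 + 0.2 * (co$yy > 0)  # nonuniform lifetime
  x <- phan$activity
  cfg <- recon_config(n_iterations = 17, n_subsets = 3,
                      gamma_mode = "fixed")
  run <- function(qmat) {
    y <- forward_project(grid_with_values(grid, qmat * x), geom)
    z <- forward_project(grid_with_values(grid, qmat * x * m_true), geom)
    xh <- mlem_activity(y, geom, grid, cfg)
    wh <- tw_mlem(z, geom, grid, cfg)
    form_lifetime_image(wh, xh, cfg = cfg)$m
  }
  m1 <- run(matrix(1, grid$nx, grid$ny))
  mq <- run(q)
  # invariance holds in the interiors of the modified-efficiency regions;
  # a finite-iteration transient lives on the efficiency step itself
  interior <- co$xx^2 + co$yy^2 <= 18^2 & abs(co$xx) > 4
  expect_lt(max(abs(m1$values[interior] - mq$values[interior])), 0.01)
})

test_that("type I randoms correction restores the no-randoms lifetime", {
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  rois <- phantom_rois(phan, margin = 5)
  cfg <- recon_config(n_iterations = 2, n_subsets = 3)
  # same seed: the true-event substream is identical in both runs
  ev_clean <- simulate_triples(phan, geom, timing_model(0.092, 0),
                               n_true = 3e5, randoms = c(0, 0, 0),
                               seed = 33)
  ev_rand <- simulate_triples(phan, geom, timing_model(0.092, 0),
                              n_true = 3e5, randoms = c(0.05, 0, 0),
                              seed = 33)
  db <- simulate_doubles(phan, geom, 6e5, seed = 44)
  cfg0 <- recon_config(n_iterations = 2, n_subsets = 3,
                       gamma_mode = "fixed", gamma = 0)
  res_clean <- reconstruct_simple(ev_clean, geom, grid, cfg0)
  res_corr <- reconstruct_simple(ev_rand, geom, grid, cfg, doubles = db)
  res_uncorr <- reconstruct_simple(ev_rand, geom, grid, cfg0)
  s_clean <- roi_stats(res_clean$m, rois$all, res_clean$mask)
  s_corr <- roi_stats(res_corr$m, rois$all, res_corr$mask)
  s_uncorr <- roi_stats(res_uncorr$m, rois$all, res_uncorr$mask)
  expect_gt(res_corr$gamma, 0)
  # correction restores the clean ROI mean ...
  expect_lt(abs(s_corr$mean - s_clean$mean), 0.02)
  # ... and removes most of the contamination bias
  expect_gt(abs(s_uncorr$mean - s_clean$mean),
            2 * abs(s_corr$mean - s_clean$mean))
})

test_that("reconstruction is deterministic given events and config", {
  geom <- mid_geom()
  grid <- mid_grid()
  phan <- mid_phantom()
  ev <- simulate_triples(phan, geom, timing_model(0.092, 0), n_true = 3e4,
                         randoms = c(0, 0, 0), seed = 55)
  cfg <- recon_config(n_iterations = 1, n_subsets = 3,
                      gamma_mode = "fixed")
  r1 <- reconstruct_simple(ev, geom, grid, cfg)
  r2 <- reconstruct_simple(ev, geom, grid, cfg)
  expect_identical(r1$m$values, r2$m$values)
})
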