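# Shared fixtures: tiny geometries for dense-matrix oracles, a mid-size
# geometry for reconstruction property tests, and the full study setup.

tiny_geom <- function(n_tof_bins = 9) {
  ring_geometry(16, 200, tof_fwhm = 0.25, n_tof_bins = n_tof_bins,
                min_arc = 4)
}

tiny_grid <- function() image_grid(8, 8, spacing = 4)

# mid-size setup for reconstruction properties: fast but representative
mid_geom <- function() ring_geometry(96, 400, tof_fwhm = 0.25)

mid_grid <- function() image_grid(32, 32, spacing = 2.5)

# small uniform-activity disk phantom on the mid grid
mid_phantom <- function(model = decay_model(c(0.3, 0.1, 0.6),
                                            c(2.5, 0.125, 0.4)),
                        grid = mid_grid(), radius = 25) {
  co <- grid_coords(grid)
  disk <- co$xx^2 + co$yy^2 <= radius^2
  activity <- matrix(0, grid$nx, grid$ny)
  activity[disk] <- 1
  labels <- matrix(0L, grid$nx, grid$ny)
  labels[disk] <- 1L
  pli_phantom(grid, activity, labels,
              regions = list(all = list(model = model, activity = 1,
                             shape = list(kind = "disk", centre = c(0, 0),
                                          radius = radius))),
              region_ids = c(all = 1L))
}

# study conditions: the rodent phantom on the default scanner
study_geom <- function() ring_geometry(384, 520, tof_fwhm = 0.25)
study_grid <- function() image_grid(72, 72, spacing = 1.25)

# one full study realisation; returns ROI tables for both methods
run_study_seed <- function(seed, n_true = 1e6, randoms = c(0.049, 0.001,
                           0.00003), n_doubles = 2e6,
                           geom = study_geom(), grid = study_grid()) {
  phan <- rodent_phantom(grid)
  rois <- phantom_rois(phan)
  ev <- simulate_triples(phan, geom, timing_model(0.092, 0),
                         n_true = n_true, randoms = randoms, seed = seed)
  db <- simulate_doubles(phan, geom, n_doubles, seed = seed + 5000L)
  cfg <- recon_config(n_iterations = 2, n_subsets = 3)
  simple <- reconstruct_simple(ev, geom, grid, cfg, db, rois$background)
  tofbp <- reconstruct_tofbp(ev, geom, grid, cfg, db, rois$background)
  list(simple = evaluate_rois(simple, rois),
       tofbp = evaluate_rois(tofbp, rois))
}

roi_mean <- function(tab, roi) tab$mean[tab$roi == roi]

expect_images_equal <- function(a, b, tol) {
  expect_lt(max(abs(a$values - b$values)), tol)
}
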