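test_that("geometry constructor validates and enumerates LORs", {
  geom <- tiny_geom()
  expect_equal(geom$n_tof_bins %% 2L, 1L)
  expect_true(all(geom$lor_a < geom$lor_b))
  arc <- pmin((geom$lor_b - geom$lor_a) %% geom$n_crystals,
              (geom$lor_a - geom$lor_b) %% geom$n_crystals)
  expect_true(all(arc >= geom$min_arc))
  expect_error(ring_geometry(7, 200, 0.25), "even")
  expect_error(ring_geometry(16, 200, 0.25, n_tof_bins = 8), "odd")
  # flat bin indexing is LOR-major, 0-based, centred
  expect_equal(flat_bin(1, 0, geom), (geom$n_tof_bins - 1L) %/% 2L)
  expect_equal(flat_bin(2, 0, geom) - flat_bin(1, 0, geom),
               geom$n_tof_bins)
  expect_error(flat_bin(1, 100, geom), "range")
})

test_that("system rows are symmetric for central LORs and reduce to lengths", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  # diametral LOR through the centre, central TOF bin
  lor <- which(((geom$lor_b - geom$lor_a) %% geom$n_crystals) ==
               geom$n_crystals / 2)[1]
  row <- system_row(lor, 0, geom, grid)
  expect_gt(length(row$vox), 0)
  expect_lt(max(abs(row$w - rev(row$w))), 1e-9)
  # huge TOF fwhm: kernel flat across the grid -> row proportional to lengths
  geom_wide <- ring_geometry(16, 200, tof_fwhm = 1e5, n_tof_bins = 9,
                             min_arc = 4)
  row_wide <- system_row(lor, 0, geom_wide, grid)
  geom_ntof1 <- ring_geometry(16, 200, tof_fwhm = 0, n_tof_bins = 1,
                              tof_bin_width = 1e6, min_arc = 4)
  row_len <- system_row(lor, 0, geom_ntof1, grid)  # pure intersection length
  ratio <- row_wide$w / row_len$w
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("TOF kernel factors sum to 1 across bins for interior voxels", {
  geom <- tiny_geom(n_tof_bins = 41)   # bins cover grid + 5.5 sigma
  grid <- tiny_grid()
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  lor <- which(((geom$lor_b - geom$lor_a) %% geom$n_crystals) ==
               geom$n_crystals / 2)[1]
  base <- system_row(lor, 0, geom, grid)
  tot <- numeric(length(base$vox))
  for (k in -k0:k0) {
    row <- system_row(lor, k, geom, grid)
    expect_identical(row$vox, base$vox)
    tot <- tot + row$w
  }
  # dividing by intersection length leaves the per-voxel kernel sum
  len <- system_row(lor, 0,
                    ring_geometry(16, 200, 0, n_tof_bins = 1,
                                  tof_bin_width = 1e6, min_arc = 4),
                    grid)$w
  expect_lt(max(abs(tot / len - 1)), 1e-6)
})

test_that("forward and backward match the dense system-matrix oracle", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  H <- dense_system_matrix(geom, grid)
  set.seed(1)
  x <- matrix(runif(grid$nx * grid$ny), grid$nx, grid$ny)
  s <- runif(n_bins(geom))
  fx <- forward_project(grid_with_values(grid, x), geom)$values
  expect_lt(max(abs(fx - as.numeric(H %*% as.numeric(x)))), 1e-10)
  bs <- back_project(s, geom, grid)$values
  expect_lt(max(abs(as.numeric(bs) - as.numeric(crossprod(H, s)))), 1e-10)
  # zero image -> zero sinogram; zero sinogram -> zero image
  expect_equal(sum(abs(forward_project(grid, geom)$values)), 0)
  expect_equal(sum(abs(back_project(numeric(n_bins(geom)), geom,
                                    grid)$values)), 0)
})

test_that("forward projection of a hot voxel is supported only on its LORs", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  x <- matrix(0, 8, 8); x[3, 6] <- 1
  fx <- forward_project(grid_with_values(grid, x), geom)$values
  expect_gt(sum(fx), 0)
  hot_lors <- unique((which(fx > 0) - 1L) %/% geom$n_tof_bins + 1L)
  co <- grid_coords(grid)
  px <- co$x[3]; py <- co$y[6]
  for (l in hot_lors) {
    ax <- geom$crystal_x[geom$lor_a[l]]; ay <- geom$crystal_y[geom$lor_a[l]]
    bx <- geom$crystal_x[geom$lor_b[l]]; by <- geom$crystal_y[geom$lor_b[l]]
    d <- abs((bx - ax) * (ay - py) - (ax - px) * (by - ay)) /
      sqrt((bx - ax)^2 + (by - ay)^2)
    expect_lt(d, grid$spacing)  # chord passes through/next to the voxel
  }
})

test_that("forward and backward are exactly adjoint", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(rnorm(64), 8, 8)
    s <- rnorm(n_bins(geom))
    lhs <- sum(forward_project(grid_with_values(grid, x), geom)$values * s)
    rhs <- sum(x * back_project(s, geom, grid)$values)
    expect_lt(abs(lhs - rhs), 1e-10 * max(abs(lhs), 1))
  }
})

test_that("sensitivity image equals the backprojection of a unit sinogram", {
  geom <- tiny_geom()
  grid <- tiny_grid()
  sens <- sensitivity_image(geom, grid)$values
  ones <- back_project(rep(1, n_bins(geom)), geom, grid)$values
  expect_lt(max(abs(sens - ones)), 1e-9)
  # subsets partition the LORs: subset sensitivities sum to the total
  parts <- Reduce(`+`, lapply(1:3, function(s)
    sensitivity_image(geom, grid, s, 3)$values))
  expect_lt(max(abs(parts - sens)), 1e-9)
})

test_that("rotating the phantom by a crystal-aligned angle permutes LORs", {
  # a quarter-turn (n_crystals/4 crystal pitches) maps voxels to voxels and
  # crystals to crystals, so the sinogram must permute exactly
  geom <- tiny_geom()
  grid <- image_grid(9, 9, spacing = 4)
  set.seed(3)
  x <- matrix(runif(81), 9, 9)
  xr <- t(x)[9:1, ]                    # counter-clockwise quarter turn
  fx <- forward_project(grid_with_values(grid, x), geom)$values
  fr <- forward_project(grid_with_values(grid, xr), geom)$values
  q <- geom$n_crystals / 4L
  perm <- numeric(length(fx))
  for (l in seq_len(geom$n_lors)) {
    a <- (geom$lor_a[l] - 1L + q) %% geom$n_crystals + 1L
    b <- (geom$lor_b[l] - 1L + q) %% geom$n_crystals + 1L
    l2 <- geom$lor_lookup[min(a, b), max(a, b)]
    expect_false(is.na(l2))
    src <- ((l - 1) * geom$n_tof_bins + 1):(l * geom$n_tof_bins)
    dst <- ((l2 - 1) * geom$n_tof_bins + 1):(l2 * geom$n_tof_bins)
    if (min(a, b) != a) dst <- rev(dst)  # chord direction flips with order
    perm[dst] <- fx[src]
  }
  expect_lt(max(abs(fr - perm)), 1e-9 * max(fx))
})
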