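test_that("parameter validation enforces the documented ranges", {
  expect_error(sart_params(lam = 0), "lam")
  expect_error(sart_params(lam = 2.5), "lam")
  expect_error(sart_params(lam_red = 0), "lam_red")
  expect_error(sart_params(n_iterations = 0), "n_iterations")
})

test_that("a single ray through a single voxel solves in one update", {
  # voxel of edge 2 mm -> chord a = 2; y = a * x_true
  grid <- volume_grid(c(1, 1, 1), c(2, 2, 2))
  geom <- cone_beam_geometry(40, 20, n_views = 1, detector_shape = c(1, 1),
                             detector_pixel = c(1, 1))
  x_true <- 0.7
  y <- forward_project(ct_volume(grid, x_true), geom, check_fov = FALSE)
  expect_equal(y$frames[1], 2 * x_true, tolerance = 1e-12)
  upd <- sart_view_update(ct_volume(grid, 0), y, 1, lam = 1)
  expect_equal(upd$values[1], x_true, tolerance = 1e-12)
})

test_that("the exact solution is a fixed point of every view update", {
  grid <- small_grid(12, 2)
  geom <- small_geometry(n_views = 4)
  truth <- make_phantom(head_phantom_specs(grid), grid)
  proj <- forward_project(truth, geom, check_fov = FALSE)
  tables <- cbctrec:::sart_tables(geom, grid)
  for (v in 1:4) {
    upd <- sart_view_update(truth, proj, v, lam = 1, tables = tables)
    expect_equal(upd$values, truth$values, tolerance = 1e-12)
  }
  out <- sart_reconstruct(proj, grid, sart_params(n_iterations = 2),
                          initial = truth)
  expect_equal(out$values, truth$values, tolerance = 1e-10)
})

test_that("SART converges to the direct solve on a full-rank 2x2 system", {
  # four views of three slightly oblique rays each: an odd ray count per
  # view avoids the mirror-paired-ray degeneracy that stalls per-view
  # subset updates on toy systems
  grid <- volume_grid(c(2, 2, 1), c(1, 1, 1))
  geom <- cone_beam_geometry(40, 20, n_views = 4,
                             view_angles = c(0.3, 1.2, 2.1, 3.9),
                             detector_shape = c(1, 3),
                             detector_pixel = c(1, 1.1))
  A <- dense_system_matrix(geom, grid)
  expect_equal(qr(A)$rank, 4)
  x_true <- c(0.3, 0.8, 0.5, 0.1)
  y <- array(A %*% x_true, dim = c(1, 3, 4))
  out <- sart_reconstruct(projection_set(geom, y), grid,
                          sart_params(lam = 1, lam_red = 0.99,
                                      n_iterations = 500, nonneg = FALSE))
  direct <- qr.solve(A, as.numeric(y))   # consistent, so exact
  expect_equal(as.numeric(out$values), direct, tolerance = 1e-6)
})

test_that("zero data from a zero start stays zero", {
  grid <- small_grid(8)
  geom <- small_geometry(n_views = 2)
  out <- sart_reconstruct(projection_set(geom, 0), grid,
                          sart_params(n_iterations = 2))
  expect_true(all(out$values == 0))
  expect_error(sart_reconstruct(projection_set(geom, 0), small_grid(4),
                                sart_params(), initial = ct_volume(small_grid(8), 0)),
               "grid mismatch")
})

test_that("residual norm decreases monotonically on consistent data", {
  grid <- small_grid(16, 2)
  geom <- small_geometry(n_views = 8)
  truth <- make_phantom(head_phantom_specs(grid), grid)
  proj <- forward_project(truth, geom, check_fov = FALSE)
  out <- sart_reconstruct(proj, grid, sart_params(n_iterations = 10))
  res <- attr(out, "history")$residual_norm
  expect_length(res, 10)
  expect_true(all(diff(res) < 0))
})

test_that("reconstruction is bitwise deterministic", {
  grid <- small_grid(10, 2)
  geom <- small_geometry(n_views = 4)
  proj <- forward_project(ball_phantom(grid), geom, check_fov = FALSE)
  a <- sart_reconstruct(proj, grid, sart_params(n_iterations = 3))
  b <- sart_reconstruct(proj, grid, sart_params(n_iterations = 3))
  expect_identical(a$values, b$values)
})

test_that("a view whose rays all miss the volume warns and is a no-op", {
  geom <- small_geometry(n_views = 1, det = c(2, 2), pitch = c(1, 1))
  geom$detector_offset <- c(500, 0)
  grid <- small_grid(8)
  proj <- projection_set(geom, array(1, dim = c(2, 2, 1)))
  start <- ball_phantom(grid)
  expect_warning(out <- sart_view_update(start, proj, 1), "miss")
  expect_identical(out$values, start$values)
})
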