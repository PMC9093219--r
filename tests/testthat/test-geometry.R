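test_that("constructors validate their invariants", {
  expect_error(cone_beam_geometry(500, 600, n_views = 4),
               "dist_source_detector > dist_source_origin")
  expect_error(cone_beam_geometry(1040, 570, n_views = 0), "n_views")
  expect_error(cone_beam_geometry(1040, 570, view_angles = c(0, 7)),
               "full rotation")
  expect_error(volume_grid(c(0, 4, 4)), "shape")
  expect_error(volume_grid(c(4, 4, 4), c(1, -1, 1)), "voxel_size")
  expect_error(ct_volume(small_grid(4), array(NA_real_, dim = c(4, 4, 4))),
               "finite")
  g <- cone_beam_geometry(1040, 570, n_views = 8)
  expect_equal(g$view_angles, seq(0, 2 * pi, length.out = 9)[1:8])
})

test_that("ray missing the grid returns an empty intersection", {
  geom <- small_geometry(n_views = 1, det = c(1, 1), pitch = c(1, 1))
  # huge offset pushes the ray far outside the volume
  geom$detector_offset <- c(200, 0)
  tr <- trace_ray(geom, small_grid(8), 1, c(1, 1))
  expect_length(tr$voxel_indices, 0)
  expect_length(tr$lengths, 0)
})

test_that("axis-aligned central ray crosses a 64 mm cube in 64 unit chords", {
  geom <- cone_beam_geometry(160, 80, n_views = 1, detector_shape = c(1, 1),
                             detector_pixel = c(1, 1))
  grid <- volume_grid(c(64, 64, 64), c(1, 1, 1))
  tr <- trace_ray(geom, grid, 1, c(1, 1))
  expect_length(tr$lengths, 64)
  expect_equal(tr$lengths, rep(1, 64), tolerance = 1e-12)
  expect_equal(sum(tr$lengths), 64, tolerance = 1e-12)
  # unit cube forward projection equals the chord length
  ps <- forward_project(ct_volume(grid, 1), geom, check_fov = FALSE)
  expect_equal(ps$frames[1, 1, 1], 64, tolerance = 1e-12)
})

test_that("trace_ray agrees with the sorted-plane-crossings oracle", {
  geom <- small_geometry(n_views = 3, det = c(7, 7), pitch = c(3.1, 2.7),
                         angles = c(0.37, 2.11, 4.93))
  grid <- volume_grid(c(11, 13, 9), c(1.3, 0.9, 1.7), origin = c(0.5, -1, 2))
  for (v in 1:3) {
    for (px in list(c(1, 1), c(4, 4), c(7, 2), c(3, 6))) {
      tr <- trace_ray(geom, grid, v, px)
      ends <- ray_endpoints(geom, v, px[1], px[2])
      or <- oracle_trace(grid, ends$src, ends$det)
      expect_equal(tr$voxel_indices, or$voxel_indices)
      expect_equal(tr$lengths, or$lengths, tolerance = 1e-9)
    }
  }
})

test_that("trace_ray validates indices", {
  geom <- small_geometry(n_views = 2)
  grid <- small_grid(8)
  expect_error(trace_ray(geom, grid, 3, c(1, 1)), "view index")
  expect_error(trace_ray(geom, grid, 1, c(0, 1)), "pixel index")
  expect_error(trace_ray(geom, grid, 1, c(1, 25)), "pixel index")
})

test_that("forward projection is linear and matches the explicit matrix", {
  set.seed(11)
  geom <- small_geometry(n_views = 4, det = c(10, 10), pitch = c(5, 5))
  grid <- small_grid(16, 2)
  A <- dense_system_matrix(geom, grid)
  x <- array(runif(16^3), dim = grid$shape)
  ps <- forward_project(ct_volume(grid, x), geom, check_fov = FALSE)
  expect_equal(flatten_frames(ps$frames), as.numeric(A %*% as.numeric(x)),
               tolerance = 1e-12)
  # linearity: A(alpha x1 + x2) = alpha A x1 + A x2
  x2 <- array(runif(16^3), dim = grid$shape)
  lhs <- forward_project(ct_volume(grid, 2.5 * x + x2), geom,
                         check_fov = FALSE)$frames
  rhs <- 2.5 * ps$frames +
    forward_project(ct_volume(grid, x2), geom, check_fov = FALSE)$frames
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # zero volume projects to zero
  z <- forward_project(ct_volume(grid, 0), geom, check_fov = FALSE)
  expect_true(all(z$frames == 0))
})

test_that("back projection is the exact adjoint of forward projection", {
  set.seed(12)
  geom <- small_geometry(n_views = 8)
  grid <- volume_grid(c(32, 32, 32), c(1, 1, 1))
  x <- ct_volume(grid, array(runif(32^3), dim = grid$shape))
  y <- array(runif(24 * 24 * 8), dim = c(24, 24, 8))
  ax <- forward_project(x, geom, check_fov = FALSE)$frames
  aty <- back_project(projection_set(geom, y), grid)$values
  gap <- abs(sum(ax * y) - sum(x$values * aty)) /
    (sqrt(sum(ax^2)) * sqrt(sum(y^2)))
  expect_lt(gap, 1e-10)
})

test_that("single-ray back projection has the support of that ray", {
  geom <- small_geometry(n_views = 2, det = c(5, 5), pitch = c(8, 8))
  grid <- small_grid(16, 2)
  frames <- array(0, dim = c(5, 5, 2))
  frames[3, 2, 2] <- 1.7
  bp <- back_project(projection_set(geom, frames), grid)
  tr <- trace_ray(geom, grid, 2, c(3, 2))
  expect_gt(length(tr$voxel_indices), 0)
  expect_equal(which(bp$values != 0), sort(tr$voxel_indices))
  expect_equal(bp$values[tr$voxel_indices], 1.7 * tr$lengths,
               tolerance = 1e-12)
  # all-zero projections give the zero volume
  z <- back_project(projection_set(geom, 0), grid)
  expect_true(all(z$values == 0))
})

test_that("row sums equal forward projection of ones and conserve chords", {
  geom <- small_geometry(n_views = 5, det = c(12, 12), pitch = c(4, 4))
  grid <- volume_grid(c(9, 9, 9), c(1.5, 1.5, 1.5))
  rs <- row_sums(geom, grid)
  ones <- forward_project(ct_volume(grid, 1), geom, check_fov = FALSE)
  expect_equal(rs$ray, ones$frames, tolerance = 1e-12)
  expect_true(all(rs$ray >= 0))
  expect_true(all(rs$voxel >= 0))
  # Siddon length conservation: each row sum equals the entry-exit chord
  for (v in c(1, 3, 5)) {
    for (px in list(c(6, 6), c(1, 12), c(9, 3))) {
      ends <- ray_endpoints(geom, v, px[1], px[2])
      chord <- oracle_chord(grid, ends$src, ends$det)
      expect_equal(rs$ray[px[1], px[2], v], chord,
                   tolerance = 1e-9 * max(1, chord))
    }
  }
})

test_that("spherically symmetric phantoms project identically across views", {
  grid <- volume_grid(c(20, 20, 20), c(1, 1, 1))
  ball <- ball_phantom(grid)
  # exact grid symmetry at quarter turns
  geom4 <- small_geometry(n_views = 4, det = c(16, 16), pitch = c(3, 3),
                          angles = c(0, pi / 2, pi, 3 * pi / 2))
  fr <- forward_project(ball, geom4, check_fov = FALSE)$frames
  for (v in 2:4)
    expect_equal(fr[, , v], fr[, , 1], tolerance = 1e-10)
  # at arbitrary angles the voxelized ball is only symmetric up to its
  # voxelization error; the projected mass per view agrees to ~1% at this
  # resolution and tightens as the grid is refined
  grid_f <- volume_grid(c(48, 48, 48), c(0.5, 0.5, 0.5))
  ball_f <- make_phantom(list(ellipsoid_spec(c(0, 0, 0), rep(6, 3),
                                             value_delta = 1)), grid_f)
  geom8 <- small_geometry(n_views = 8, det = c(16, 16), pitch = c(3, 3))
  fr8 <- forward_project(ball_f, geom8, check_fov = FALSE)$frames
  sums <- apply(fr8, 3, sum)
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.02)
})

test_that("the FOV check warns when the volume projects off the panel", {
  geom <- small_geometry(n_views = 1, det = c(4, 4), pitch = c(1, 1))
  expect_warning(forward_project(ball_phantom(small_grid(16)), geom),
                 "detector")
  geom_ok <- small_geometry(n_views = 1)
  expect_silent(forward_project(ball_phantom(small_grid(8)), geom_ok))
})
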