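#' Trace one X-ray through the voxel grid
#'
#' Siddon-style parametric traversal of the segment from the source to the
#' centre of one detector pixel.  Returns every voxel the segment crosses
#' together with its exact chord length `a_ij` (mm); an empty result when the
#' segment misses the grid.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param grid A [volume_grid()].
#' @param view View index (1-based).
#' @param det_pixel Detector pixel `(row, col)` (1-based).
#' @return A list with `voxel_indices` (1-based flat indices into the volume
#'   array) and `lengths` (mm).
#' @examples
#' geom <- cone_beam_geometry(160, 80, n_views = 1, detector_shape = c(1, 1))
#' ray <- trace_ray(geom, volume_grid(c(64, 64, 64)), 1, c(1, 1))
#' sum(ray$lengths)  # 64 mm chord through the cube
#' @export
trace_ray <- function(geometry, grid, view, det_pixel) {
  stopifnot(inherits(geometry, "cone_beam_geometry"),
            inherits(grid, "volume_grid"))
  view <- as.integer(view)
  det_pixel <- as.integer(det_pixel)
  if (view < 1 || view > geometry$n_views) stop("view index out of range")
  if (length(det_pixel) != 2 ||
      det_pixel[1] < 1 || det_pixel[1] > geometry$detector_shape[1] ||
      det_pixel[2] < 1 || det_pixel[2] > geometry$detector_shape[2])
    stop("detector pixel index out of range")
  vb <- view_basis(geometry, view)
  cpp_trace_ray(grid$shape, grid$voxel_size, grid_corner(grid),
                vb$src, vb$det00, vb$eu, vb$ev,
                det_pixel[1] - 1L, det_pixel[2] - 1L)
}

#' Forward projection y = A x
#'
#' Computes the cone-beam line integrals of a volume over every view of a
#' geometry using on-the-fly Siddon traversal; the system matrix is never
#' materialized.
#'
#' @param volume A [ct_volume()].
#' @param geometry A [cone_beam_geometry()].
#' @param check_fov Warn if the volume may project outside the detector.
#' @return A [projection_set()].
#' @export
forward_project <- function(volume, geometry, check_fov = TRUE) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(geometry, "cone_beam_geometry"))
  if (any(!is.finite(volume$values))) stop("volume values must be finite")
  if (check_fov) check_fov(geometry, volume$grid)
  grid <- volume$grid
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  frames <- array(0, dim = c(nr, nc, geometry$n_views))
  for (v in seq_len(geometry$n_views)) {
    vb <- view_basis(geometry, v)
    frames[, , v] <- cpp_forward_view(volume$values, grid$shape,
                                      grid$voxel_size, grid_corner(grid),
                                      vb$src, vb$det00, vb$eu, vb$ev, nr, nc)
  }
  projection_set(geometry, frames)
}

#' Back projection A^T y
#'
#' Adjoint of [forward_project()] with exactly the same intersection lengths
#' `a_ij` (matched projector pair).
#'
#' @param projections A [projection_set()].
#' @param grid A [volume_grid()].
#' @return A [ct_volume()] holding `A^T y`.
#' @export
back_project <- function(projections, grid) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"))
  if (any(!is.finite(projections$frames)))
    stop("projection frames must be finite")
  geometry <- projections$geometry
  acc <- numeric(prod(grid$shape))
  for (v in seq_len(geometry$n_views)) {
    vb <- view_basis(geometry, v)
    acc <- acc + cpp_back_view(projections$frames[, , v, drop = TRUE],
                               grid$shape, grid$voxel_size, grid_corner(grid),
                               vb$src, vb$det00, vb$eu, vb$ev)
  }
  ct_volume(grid, array(acc, dim = grid$shape))
}

#' Row and column sums of the system matrix
#'
#' Per-ray sums `sum_j a_ij` (the denominators of the SART ray corrections;
#' equal to the forward projection of the all-ones volume) and per-voxel sums
#' `sum_i a_ij` restricted to each view subset.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param grid A [volume_grid()].
#' @return A list with `ray` (array `(rows, cols, n_views)`) and `voxel`
#'   (array `(nx, ny, nz, n_views)`).  Rays with a zero row sum miss the grid
#'   and are excluded from algebraic updates.
#' @export
row_sums <- function(geometry, grid) {
  stopifnot(inherits(geometry, "cone_beam_geometry"),
            inherits(grid, "volume_grid"))
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  ray <- array(0, dim = c(nr, nc, geometry$n_views))
  voxel <- array(0, dim = c(grid$shape, geometry$n_views))
  for (v in seq_len(geometry$n_views)) {
    vb <- view_basis(geometry, v)
    ray[, , v] <- cpp_ray_sums_view(grid$shape, grid$voxel_size,
                                    grid_corner(grid), vb$src, vb$det00,
                                    vb$eu, vb$ev, nr, nc)
    voxel[, , , v] <- cpp_voxel_sums_view(grid$shape, grid$voxel_size,
                                          grid_corner(grid), vb$src, vb$det00,
                                          vb$eu, vb$ev, nr, nc)
  }
  list(ray = ray, voxel = voxel)
}

# Power-iteration estimate of ||A^T A||_2 on a given grid/geometry.
# Deterministic: starts from the all-ones volume, 10 iterations.
estimate_op_norm <- function(geometry, grid, n_iter = 10) {
  v <- ct_volume(grid, 1)
  lam <- 1
  for (k in seq_len(n_iter)) {
    w <- back_project(forward_project(v, geometry, check_fov = FALSE), grid)
    lam <- sqrt(sum(w$values^2))
    if (lam == 0) return(0)
    v <- ct_volume(grid, w$values / lam)
  }
  lam
}
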