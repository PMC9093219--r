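#' Ellipsoid component of a piecewise-constant phantom
#'
#' @param center Ellipsoid centre (mm, 3-vector, world coordinates).
#' @param semi_axes Semi-axis lengths (mm, 3-vector, all > 0).
#' @param euler_angles Rotation angles (radians, 3-vector); the ellipsoid
#'   frame is `Rz(a1) Ry(a2) Rx(a3)` applied to the world frame.
#' @param value_delta Additive attenuation contribution inside the ellipsoid.
#' @return An object of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(center, semi_axes, euler_angles = c(0, 0, 0),
                           value_delta = 1) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  euler_angles <- as.numeric(euler_angles)
  stopifnot(length(center) == 3, length(semi_axes) == 3,
            length(euler_angles) == 3, length(value_delta) == 1)
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  structure(list(center = center, semi_axes = semi_axes,
                 euler_angles = euler_angles,
                 value_delta = as.numeric(value_delta)),
            class = "ellipsoid_spec")
}

rotation_matrix <- function(a) {
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Render a piecewise-constant ellipsoid phantom
#'
#' Voxel values are the sum of `value_delta` over all ellipsoids containing
#' the voxel centre, clipped to be nonnegative.  With nested ellipsoids this
#' produces piecewise-constant anatomy whose gradient-magnitude image is
#' sparse -- the structural assumption behind TV/TpV regularization.
#'
#' @param specs A list of [ellipsoid_spec()] objects (empty list gives the
#'   zero volume).
#' @param grid A [volume_grid()].
#' @return A [ct_volume()].
#' @examples
#' vol <- make_phantom(head_phantom_specs(volume_grid(c(32, 32, 32))),
#'                     volume_grid(c(32, 32, 32)))
#' range(vol$values)
#' @export
make_phantom <- function(specs, grid) {
  stopifnot(inherits(grid, "volume_grid"), is.list(specs))
  shp <- grid$shape
  corner <- grid_corner(grid)
  xc <- corner[1] + (seq_len(shp[1]) - 0.5) * grid$voxel_size[1]
  yc <- corner[2] + (seq_len(shp[2]) - 0.5) * grid$voxel_size[2]
  zc <- corner[3] + (seq_len(shp[3]) - 0.5) * grid$voxel_size[3]
  X <- rep(xc, times = shp[2] * shp[3])
  Y <- rep(rep(yc, each = shp[1]), times = shp[3])
  Z <- rep(zc, each = shp[1] * shp[2])
  vals <- numeric(prod(shp))
  for (sp in specs) {
    stopifnot(inherits(sp, "ellipsoid_spec"))
    R <- rotation_matrix(sp$euler_angles)
    dx <- X - sp$center[1]; dy <- Y - sp$center[2]; dz <- Z - sp$center[3]
    # body-frame coordinates: u = R^T d
    u1 <- (R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz) / sp$semi_axes[1]
    u2 <- (R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz) / sp$semi_axes[2]
    u3 <- (R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz) / sp$semi_axes[3]
    inside <- (u1 * u1 + u2 * u2 + u3 * u3) <= 1
    vals[inside] <- vals[inside] + sp$value_delta
  }
  ct_volume(grid, array(pmax(vals, 0), dim = shp))
}

# nested-ellipsoid head model: value delta, semi-axes (a, b, c), centre
# (x0, y0, z0) and in-plane rotation, all in fractions of the grid
# half-extent; cumulative values lie in [0, 1]
head_table <- function() {
  m <- matrix(c(
    1.0,  0.6900, 0.920, 0.810,  0.00,  0.000,  0.00,   0,
   -0.8,  0.6624, 0.874, 0.780,  0.00, -0.0184, 0.00,   0,
   -0.2,  0.1100, 0.310, 0.220,  0.22,  0.000,  0.00, -18,
   -0.2,  0.1600, 0.410, 0.280, -0.22,  0.000,  0.00,  18,
    0.1,  0.2100, 0.250, 0.410,  0.00,  0.350, -0.15,   0,
    0.1,  0.0460, 0.046, 0.050,  0.00,  0.100,  0.25,   0,
    0.1,  0.0460, 0.046, 0.050,  0.00, -0.100,  0.25,   0,
    0.1,  0.0460, 0.023, 0.050, -0.08, -0.605,  0.00,   0,
    0.1,  0.0230, 0.023, 0.020,  0.00, -0.606,  0.00,   0,
    0.1,  0.0230, 0.046, 0.020,  0.06, -0.605,  0.00,   0), ncol = 8,
    byrow = TRUE)
  colnames(m) <- c("delta", "a", "b", "c", "x0", "y0", "z0", "phi_deg")
  m
}

#' Built-in head phantom specification
#'
#' A 3D Shepp-Logan-style head: ten nested ellipsoids (skull shell,
#' brain, ventricles, small lesions) with cumulative attenuation values in
#' `[0, 1]`, scaled to the half-extent of the supplied grid.
#'
#' @param grid A [volume_grid()]; the phantom is scaled to fill it.
#' @return A list of [ellipsoid_spec()] objects, usable with [make_phantom()].
#' @export
head_phantom_specs <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  half <- grid$shape * grid$voxel_size / 2
  tb <- head_table()
  lapply(seq_len(nrow(tb)), function(i) {
    ellipsoid_spec(center = tb[i, c("x0", "y0", "z0")] * half + grid$origin,
                   semi_axes = tb[i, c("a", "b", "c")] * half,
                   euler_angles = c(tb[i, "phi_deg"] * pi / 180, 0, 0),
                   value_delta = tb[i, "delta"])
  })
}

#' Simulation configuration
#'
#' Bundles a phantom description, grid, scan geometry, noise model and seed
#' for reproducible projection simulation.
#'
#' @param phantom List of [ellipsoid_spec()]; `NULL` selects the built-in
#'   head phantom for the grid.
#' @param grid A [volume_grid()].
#' @param geometry A [cone_beam_geometry()].
#' @param noise `"none"` (default) or `"poisson"`.
#' @param photons_per_ray Unattenuated photon count `I0` per detector pixel
#'   (required and > 0 for Poisson noise).
#' @param seed Integer RNG seed used when noise is simulated.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(grid, geometry, phantom = NULL,
                              noise = c("none", "poisson"),
                              photons_per_ray = 1e5, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(grid, "volume_grid"),
            inherits(geometry, "cone_beam_geometry"))
  if (is.null(phantom)) phantom <- head_phantom_specs(grid)
  if (noise == "poisson" &&
      (!is.numeric(photons_per_ray) || photons_per_ray <= 0))
    stop("photons_per_ray must be > 0 for poisson noise")
  structure(list(phantom = phantom, grid = grid, geometry = geometry,
                 noise = noise, photons_per_ray = as.numeric(photons_per_ray),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate sparse-angle projection data
#'
#' Renders the phantom and forward-projects it with the Siddon line driver.
#' Under the Poisson model each line integral `y` is replaced by
#' `-log(Poisson(I0 exp(-y)) / I0)` (zero counts are floored at 0.5 photons);
#' the noiseless default returns exactly `forward_project()` of the phantom.
#'
#' @param config A [simulation_config()].
#' @return A list with `ground_truth` (a [ct_volume()]) and `projections`
#'   (a [projection_set()]).
#' @export
simulate_projections <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- make_phantom(config$phantom, config$grid)
  proj <- forward_project(truth, config$geometry)
  if (config$noise == "poisson") {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(config$seed)
    i0 <- config$photons_per_ray
    counts <- stats::rpois(length(proj$frames), i0 * exp(-proj$frames))
    counts[counts == 0] <- 0.5
    proj$frames <- array(-log(counts / i0), dim = dim(proj$frames))
  }
  list(ground_truth = truth, projections = proj)
}
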