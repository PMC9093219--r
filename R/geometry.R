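#' Circular cone-beam scan geometry
#'
#' Describes a flat-panel cone-beam CT acquisition on a circular source
#' trajectory in the `z = 0` plane: at angle `theta` the source sits at
#' `(d_so cos(theta), d_so sin(theta), 0)` and the detector panel is
#' perpendicular to the source--isocenter line on the far side, centred on it
#' unless offsets are given.  Together with a [volume_grid()] this fixes every
#' intersection length `a_ij` of the system matrix `y = A x`.
#'
#' @param dist_source_detector Source-to-detector distance (mm).
#' @param dist_source_origin Source-to-isocenter distance (mm); must be
#'   smaller than `dist_source_detector`.
#' @param n_views Number of view angles.  Ignored when `view_angles` is given.
#' @param view_angles Optional vector of view angles in radians, each within
#'   one full rotation.  Default: `n_views` equispaced angles over `[0, 2*pi)`.
#' @param detector_shape Integer `(rows, cols)` of the flat panel.
#' @param detector_pixel Detector pixel pitch `(du, dv)` in mm.
#' @param detector_offset In-plane panel offset `(u0, v0)` in mm (default 0).
#' @return An object of class `cone_beam_geometry`.
#' @examples
#' geom <- cone_beam_geometry(1040, 570, n_views = 32,
#'                            detector_shape = c(128, 128),
#'                            detector_pixel = c(1.6272, 1.6272))
#' geom
#' @seealso [forward_project()], [volume_grid()]
#' @export
cone_beam_geometry <- function(dist_source_detector, dist_source_origin,
                               n_views = NULL, view_angles = NULL,
                               detector_shape = c(128L, 128L),
                               detector_pixel = c(1, 1),
                               detector_offset = c(0, 0)) {
  stopifnot(is.numeric(dist_source_detector), length(dist_source_detector) == 1,
            is.numeric(dist_source_origin), length(dist_source_origin) == 1)
  if (!(dist_source_detector > dist_source_origin && dist_source_origin > 0))
    stop("need dist_source_detector > dist_source_origin > 0")
  if (is.null(view_angles)) {
    if (is.null(n_views)) stop("supply n_views or view_angles")
    n_views <- as.integer(n_views)
    if (n_views < 1) stop("n_views must be >= 1")
    view_angles <- seq(0, 2 * pi, length.out = n_views + 1L)[seq_len(n_views)]
  } else {
    view_angles <- as.numeric(view_angles)
    if (length(view_angles) < 1) stop("need at least one view angle")
    if (any(!is.finite(view_angles)) ||
        any(view_angles <= -2 * pi) || any(view_angles >= 2 * pi))
      stop("view_angles must be finite and strictly within one full rotation")
    n_views <- length(view_angles)
  }
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2 || any(detector_shape < 1))
    stop("detector_shape must be two positive integers (rows, cols)")
  detector_pixel <- as.numeric(detector_pixel)
  if (length(detector_pixel) != 2 || any(detector_pixel <= 0))
    stop("detector_pixel must be two positive pitches (du, dv) in mm")
  detector_offset <- as.numeric(detector_offset)
  if (length(detector_offset) != 2 || any(!is.finite(detector_offset)))
    stop("detector_offset must be two finite offsets (u0, v0) in mm")
  structure(
    list(dist_source_detector = as.numeric(dist_source_detector),
         dist_source_origin = as.numeric(dist_source_origin),
         n_views = n_views, view_angles = view_angles,
         detector_shape = detector_shape, detector_pixel = detector_pixel,
         detector_offset = detector_offset),
    class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat("Cone-beam geometry (circular trajectory)\n")
  cat(sprintf("  source-detector: %g mm, source-origin: %g mm\n",
              x$dist_source_detector, x$dist_source_origin))
  cat(sprintf("  views: %d over [%.4f, %.4f] rad\n", x$n_views,
              min(x$view_angles), max(x$view_angles)))
  cat(sprintf("  detector: %d x %d px at (%g, %g) mm, offset (%g, %g) mm\n",
              x$detector_shape[1], x$detector_shape[2],
              x$detector_pixel[1], x$detector_pixel[2],
              x$detector_offset[1], x$detector_offset[2]))
  invisible(x)
}

#' 3D voxel lattice
#'
#' A voxel grid in world millimetres.  The grid is centred on the isocenter
#' plus `origin`; voxel indexing follows R array order with world `x` along
#' the first dimension.
#'
#' @param shape Integer `(nx, ny, nz)` voxel counts.
#' @param voxel_size Voxel edge lengths `(sx, sy, sz)` in mm.
#' @param origin Offset (mm) of the grid centre from the isocenter.
#' @return An object of class `volume_grid`.
#' @examples
#' volume_grid(c(64, 64, 64), c(1, 1, 1))
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(shape) != 3 || any(shape < 1))
    stop("shape must be three integers >= 1")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be three finite offsets (mm)")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("Volume grid: %d x %d x %d voxels at (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# world-space min corner of a grid
grid_corner <- function(grid) {
  grid$origin - grid$shape * grid$voxel_size / 2
}

grid_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

#' Attenuation volume on a grid
#'
#' Pairs a [volume_grid()] with per-voxel linear attenuation values `x`
#' (unitless attenuation coefficient; the unknown of `y = A x`).
#'
#' @param grid A [volume_grid()].
#' @param values A numeric array of dimension `grid$shape`, or a scalar which
#'   is recycled.  All values must be finite.
#' @return An object of class `ct_volume` with elements `grid` and `values`.
#' @examples
#' vol <- ct_volume(volume_grid(c(8, 8, 8)), 0)
#' @export
ct_volume <- function(grid, values = 0) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(values) == 1) {
    values <- array(as.numeric(values), dim = grid$shape)
  } else {
    values <- as.array(values)
    if (!identical(as.integer(dim(values)), grid$shape))
      stop("values dimensions do not match grid shape")
    storage.mode(values) <- "double"
  }
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(grid = grid, values = values), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume: %d x %d x %d voxels, values in [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Projection data with its geometry
#'
#' A stack of detector frames `y` (line integrals, mm x attenuation), one
#' per view angle, together with the [cone_beam_geometry()] that produced it.
#'
#' @param geometry A [cone_beam_geometry()].
#' @param frames Numeric array `(rows, cols, n_views)`, or a scalar to fill.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(geometry, frames = 0) {
  stopifnot(inherits(geometry, "cone_beam_geometry"))
  dims <- c(geometry$detector_shape, geometry$n_views)
  if (length(frames) == 1) {
    frames <- array(as.numeric(frames), dim = dims)
  } else {
    frames <- as.array(frames)
    if (!identical(as.integer(dim(frames)), as.integer(dims)))
      stop("frames must have dimension (rows, cols, n_views)")
    storage.mode(frames) <- "double"
  }
  if (any(!is.finite(frames))) stop("projection frames must be finite")
  structure(list(geometry = geometry, frames = frames),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Projection set: %d views of %d x %d detector pixels\n",
              d[3], d[1], d[2]))
  cat(sprintf("  line-integral range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

# Per-view source position and detector basis used by the C++ traversal.
# Returns source, centre of pixel (row 1, col 1), and the per-row (ev,
# world z) / per-column (eu, in-plane tangential) step vectors in mm.
view_basis <- function(geometry, view) {
  th <- geometry$view_angles[view]
  dso <- geometry$dist_source_origin
  ddo <- geometry$dist_source_detector - dso
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  du <- geometry$detector_pixel[1]; dv <- geometry$detector_pixel[2]
  u0 <- geometry$detector_offset[1]; v0 <- geometry$detector_offset[2]
  src <- c(dso * cos(th), dso * sin(th), 0)
  ctr <- c(-ddo * cos(th), -ddo * sin(th), 0)
  uhat <- c(-sin(th), cos(th), 0)
  vhat <- c(0, 0, 1)
  det00 <- ctr + (u0 - (nc - 1) / 2 * du) * uhat + (v0 - (nr - 1) / 2 * dv) * vhat
  list(src = src, det00 = det00, eu = du * uhat, ev = dv * vhat)
}

# Warn when the grid's bounding sphere can project outside the panel.
check_fov <- function(geometry, grid) {
  r <- sqrt(sum((grid$shape * grid$voxel_size / 2)^2)) +
    sqrt(sum(grid$origin^2))
  dso <- geometry$dist_source_origin
  if (r >= dso) {
    warning("volume bounding sphere reaches the source trajectory")
    return(invisible(FALSE))
  }
  half_proj <- geometry$dist_source_detector * tan(asin(r / dso))
  half_u <- geometry$detector_shape[2] * geometry$detector_pixel[1] / 2 -
    abs(geometry$detector_offset[1])
  half_v <- geometry$detector_shape[1] * geometry$detector_pixel[2] / 2 -
    abs(geometry$detector_offset[2])
  ok <- half_proj <= half_u && half_proj <= half_v
  if (!ok)
    warning(sprintf(paste0("volume bounding sphere (projected half-width ",
                           "%.1f mm) may exceed the detector (%.1f x %.1f mm ",
                           "half-extents); truncated projections possible"),
                    half_proj, half_u, half_v))
  invisible(ok)
}
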