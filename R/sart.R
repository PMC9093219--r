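#' SART parameters
#'
#' @param lam Relaxation factor `lambda`, `0 < lambda <= 2` (default 1, the
#'   published operating point).
#' @param lam_red Multiplicative relaxation decay per full pass over the
#'   views, `0 < lam_red <= 1` (default 0.99).
#' @param n_iterations Number of full passes over all view angles.
#' @param nonneg Clamp the iterate to `>= 0` after each view update.
#' @return An object of class `sart_params`.
#' @export
sart_params <- function(lam = 1, lam_red = 0.99, n_iterations = 30L,
                        nonneg = TRUE) {
  if (!(lam > 0 && lam <= 2)) stop("need 0 < lam <= 2")
  if (!(lam_red > 0 && lam_red <= 1)) stop("need 0 < lam_red <= 1")
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(lam = as.numeric(lam), lam_red = as.numeric(lam_red),
                 n_iterations = n_iterations, nonneg = isTRUE(nonneg)),
            class = "sart_params")
}

# Precompute per-view ray sums (sum_j a_ij) and voxel sums (sum_{i in view}
# a_ij); reused across every SART pass since the geometry is fixed.
sart_tables <- function(geometry, grid) {
  rs <- row_sums(geometry, grid)
  lapply(seq_len(geometry$n_views), function(v) {
    ray <- rs$ray[, , v, drop = TRUE]
    vox <- rs$voxel[, , , v, drop = TRUE]
    list(ray = ray, vox = vox, active = ray > 0, vb = view_basis(geometry, v))
  })
}

#' One SART update over a single view subset
#'
#' Applies the simultaneous correction for all rays at one view angle:
#' `x_j <- x_j + lambda * sum_i mu_i a_ij / sum_i a_ij` with the ray
#' residuals `mu_i = (y_i - [A x]_i) / sum_j a_ij`.  Rays whose row sum is
#' zero miss the volume and are excluded.
#'
#' @param estimate Current estimate (a [ct_volume()]).
#' @param projections A [projection_set()].
#' @param view View index (1-based).
#' @param lam Relaxation factor for this update.
#' @param nonneg Clamp the result to `>= 0`.
#' @param tables Optional precomputed output of the internal per-view table
#'   builder; computed on the fly when missing.
#' @return The updated [ct_volume()].
#' @export
sart_view_update <- function(estimate, projections, view, lam = 1,
                             nonneg = TRUE, tables = NULL) {
  stopifnot(inherits(estimate, "ct_volume"),
            inherits(projections, "projection_set"))
  grid <- estimate$grid
  geometry <- projections$geometry
  if (is.null(tables)) tables <- sart_tables(geometry, grid)
  tb <- tables[[view]]
  if (!any(tb$active)) {
    warning("all rays of this view miss the volume; no update applied")
    return(estimate)
  }
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  yhat <- cpp_forward_view(estimate$values, grid$shape, grid$voxel_size,
                           grid_corner(grid), tb$vb$src, tb$vb$det00,
                           tb$vb$eu, tb$vb$ev, nr, nc)
  mu <- matrix(0, nr, nc)
  y <- projections$frames[, , view, drop = TRUE]
  mu[tb$active] <- (y[tb$active] - yhat[tb$active]) / tb$ray[tb$active]
  numer <- cpp_back_view(mu, grid$shape, grid$voxel_size, grid_corner(grid),
                         tb$vb$src, tb$vb$det00, tb$vb$eu, tb$vb$ev)
  upd <- estimate$values
  pos <- tb$vox > 0
  upd[pos] <- upd[pos] + lam * numer[pos] / tb$vox[pos]
  if (nonneg) upd <- pmax(upd, 0)
  ct_volume(grid, array(upd, dim = grid$shape))
}

#' SART reconstruction
#'
#' Cycles [sart_view_update()] over all view subsets in ascending angle
#' order; one iteration is one full pass over the views, after which the
#' relaxation factor is multiplied by `lam_red`.  Deterministic given inputs.
#'
#' @param projections A [projection_set()].
#' @param grid Reconstruction [volume_grid()].
#' @param params A [sart_params()].
#' @param initial Starting volume (default zero).
#' @param tables Optional precomputed per-view system-matrix tables.
#' @param lam0 Optional starting relaxation overriding `params$lam` (used to
#'   continue a decayed schedule across outer loops).
#' @param track_residual Record `||y - A x||_2` after each pass (costs one
#'   extra forward projection per pass; `NA` in the history when disabled).
#' @return A [ct_volume()] with attribute `"history"`: a data frame with the
#'   per-pass relaxation and residual norm `||y - A x||_2`.
#' @export
sart_reconstruct <- function(projections, grid, params = sart_params(),
                             initial = NULL, tables = NULL, lam0 = NULL,
                             track_residual = TRUE) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"), inherits(params, "sart_params"))
  if (length(projections$frames) == 0) stop("empty projections")
  geometry <- projections$geometry
  if (is.null(tables)) tables <- sart_tables(geometry, grid)
  x <- if (is.null(initial)) ct_volume(grid, 0) else initial
  stopifnot(inherits(x, "ct_volume"))
  if (!grid_equal(x$grid, grid)) stop("initial volume grid mismatch")
  lam <- if (is.null(lam0)) params$lam else lam0
  hist <- data.frame(iteration = integer(), lam = numeric(),
                     residual_norm = numeric())
  for (k in seq_len(params$n_iterations)) {
    for (v in seq_len(geometry$n_views)) {
      x <- sart_view_update(x, projections, v, lam = lam,
                            nonneg = params$nonneg, tables = tables)
    }
    rn <- NA_real_
    if (track_residual) {
      res <- forward_project(x, geometry, check_fov = FALSE)
      rn <- sqrt(sum((projections$frames - res$frames)^2))
    }
    hist <- rbind(hist, data.frame(iteration = k, lam = lam,
                                   residual_norm = rn))
    lam <- lam * params$lam_red
  }
  attr(x, "history") <- hist
  attr(x, "final_lam") <- lam
  x
}
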