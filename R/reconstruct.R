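#' Fit a CBCT reconstruction
#'
#' The package's front-end: estimates the attenuation volume from
#' sparse-angle projection data with the chosen algorithm and returns a
#' classed fit with the usual accessor methods ([coef()], [fitted()],
#' [predict()], [residuals()], [plot()], [summary()]).
#'
#' @param projections A [projection_set()] (measured or simulated).
#' @param grid Reconstruction [volume_grid()].
#' @param method `"sart"`, `"sart-tv"`, `"asd-pocs"`, `"tpv"` or
#'   `"tpv-gif"` (default).
#' @param control A parameter object matching the method ([sart_params()],
#'   [tv_baseline_params()], [tpv_params()] or [tpv_gif_params()]); `NULL`
#'   uses the published defaults.
#' @param initial Optional starting volume (methods that accept one).
#' @return An object of class `ct_recon` with elements `volume` (the
#'   [ct_volume()] estimate), `method`, `control`, `history` (per-iteration
#'   diagnostics), `projections` and `runtime` (seconds).
#' @examples
#' \donttest{
#' grid <- volume_grid(c(32, 32, 32))
#' geom <- cone_beam_geometry(1040, 570, n_views = 16,
#'                            detector_shape = c(64, 64),
#'                            detector_pixel = c(1.8, 1.8))
#' sim <- simulate_projections(simulation_config(grid, geom))
#' fit <- ct_reconstruct(sim$projections, grid, method = "sart",
#'                       control = sart_params(n_iterations = 5))
#' print(fit)
#' rmse(coef(fit), sim$ground_truth)
#' }
#' @export
ct_reconstruct <- function(projections, grid,
                           method = c("tpv-gif", "sart", "sart-tv",
                                      "asd-pocs", "tpv"),
                           control = NULL, initial = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"))
  t0 <- proc.time()[3]
  vol <- switch(method,
    "sart" = {
      if (is.null(control)) control <- sart_params()
      stopifnot(inherits(control, "sart_params"))
      sart_reconstruct(projections, grid, control, initial = initial)
    },
    "sart-tv" = {
      if (is.null(control)) control <- tv_baseline_params()
      stopifnot(inherits(control, "tv_baseline_params"))
      sart_tv_reconstruct(projections, grid, control)
    },
    "asd-pocs" = {
      if (is.null(control)) control <- tv_baseline_params()
      stopifnot(inherits(control, "tv_baseline_params"))
      asd_pocs_reconstruct(projections, grid, control)
    },
    "tpv" = {
      if (is.null(control)) control <- tpv_params()
      stopifnot(inherits(control, "tpv_params"))
      tpv_reconstruct(projections, grid, control, initial = initial)
    },
    "tpv-gif" = {
      if (is.null(control)) control <- tpv_gif_params()
      stopifnot(inherits(control, "tpv_gif_params"))
      tpv_gif_reconstruct(projections, grid, control, initial = initial)
    })
  runtime <- proc.time()[3] - t0
  structure(list(volume = ct_volume(grid, vol$values),
                 method = method, control = control,
                 history = attr(vol, "history"),
                 projections = projections,
                 runtime = unname(runtime),
                 call = match.call()),
            class = "ct_recon")
}

#' @export
print.ct_recon <- function(x, ...) {
  cat(sprintf("CBCT reconstruction (%s)\n", x$method))
  d <- x$volume$grid$shape
  cat(sprintf("  volume: %d x %d x %d voxels, values in [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$volume$values), max(x$volume$values)))
  cat(sprintf("  views: %d, detector %d x %d\n",
              x$projections$geometry$n_views,
              x$projections$geometry$detector_shape[1],
              x$projections$geometry$detector_shape[2]))
  cat(sprintf("  runtime: %.1f s\n", x$runtime))
  invisible(x)
}

#' @export
coef.ct_recon <- function(object, ...) object$volume$values

#' @export
fitted.ct_recon <- function(object, ...) {
  forward_project(object$volume, object$projections$geometry,
                  check_fov = FALSE)$frames
}

#' Predict projections from a fitted reconstruction
#'
#' Forward-projects the fitted volume, by default through the acquisition
#' geometry (giving fitted line integrals), or through a new geometry to
#' synthesize unseen views.
#'
#' @param object A `ct_recon` fit.
#' @param geometry Optional alternative [cone_beam_geometry()].
#' @param ... Unused.
#' @return A [projection_set()].
#' @export
predict.ct_recon <- function(object, geometry = NULL, ...) {
  if (is.null(geometry)) geometry <- object$projections$geometry
  forward_project(object$volume, geometry, check_fov = FALSE)
}

#' @export
residuals.ct_recon <- function(object, ...) {
  object$projections$frames - fitted(object)
}

#' @export
summary.ct_recon <- function(object, reference = NULL, ...) {
  res <- residuals(object)
  out <- list(method = object$method,
              shape = object$volume$grid$shape,
              value_range = range(object$volume$values),
              residual_norm = sqrt(sum(res^2)),
              residual_rms = sqrt(mean(res^2)),
              runtime = object$runtime,
              history = object$history,
              metrics = if (!is.null(reference))
                metrics_report(object$volume, reference) else NULL)
  class(out) <- "summary.ct_recon"
  out
}

#' @export
print.summary.ct_recon <- function(x, ...) {
  cat(sprintf("CBCT reconstruction summary (%s)\n", x$method))
  cat(sprintf("  volume %d x %d x %d, values [%.4g, %.4g]\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$value_range[1], x$value_range[2]))
  cat(sprintf("  projection residual: ||y - Ax|| = %.4g (rms %.4g)\n",
              x$residual_norm, x$residual_rms))
  cat(sprintf("  runtime %.1f s\n", x$runtime))
  if (!is.null(x$metrics)) {
    cat("  vs reference: ")
    print(x$metrics)
  }
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat(sprintf("  %d logged iterations; last row:\n", nrow(x$history)))
    print(utils::tail(x$history, 1), row.names = FALSE)
  }
  invisible(x)
}

#' Display a slice of a reconstruction
#'
#' Grayscale image of one axial (or other-axis) slice, optionally with a
#' profile line through its centre.
#'
#' @param x A `ct_recon` fit.
#' @param slice_axis Axis to slice across (default 3).
#' @param slice_index Slice to show (default: central).
#' @param profile Overlay panel with the central profile line.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ct_recon <- function(x, slice_axis = 3L, slice_index = NULL,
                          profile = FALSE, ...) {
  a <- x$volume$values
  if (is.null(slice_index))
    slice_index <- ceiling(dim(a)[slice_axis] / 2)
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[slice_axis]] <- slice_index
  sl <- as.matrix(do.call(`[`, c(list(a), idx, list(drop = TRUE))))
  if (profile) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::image(sl, col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, axes = FALSE,
                  main = sprintf("%s, slice %d", x$method, slice_index), ...)
  if (profile) {
    pr <- profile_line(a, slice_axis, slice_index,
                       line = "row", line_index = ceiling(ncol(sl) / 2))
    graphics::plot(pr$position, pr$value, type = "l",
                   xlab = "voxel position", ylab = "value",
                   main = "central profile")
  }
  invisible(x)
}
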