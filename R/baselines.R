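#' Parameters for the TV-regularized baseline reconstructors
#'
#' @param lam,lam_red SART relaxation and per-pass decay (as [sart_params()]).
#' @param alpha ASD-POCS TV step scale: each steepest-descent step moves the
#'   image by `alpha` times the magnitude of the preceding data update
#'   (published value 0.002).
#' @param lam_tv SART-TV fidelity-vs-smoothness ratio (published value 15):
#'   each TV step moves the image by `n_tv_steps / lam_tv` times the
#'   data-update magnitude, so smaller `lam_tv` smooths harder and
#'   `lam_tv = Inf` disables the TV stage, recovering plain SART.
#' @param n_tv_steps Inner TV steepest-descent steps per outer iteration.
#' @param n_iterations Outer iterations (one SART pass + one TV stage each).
#' @param nonneg Clamp iterates to `>= 0` during the SART stage.
#' @return An object of class `tv_baseline_params`.
#' @export
tv_baseline_params <- function(lam = 1, lam_red = 0.99, alpha = 0.002,
                               lam_tv = 15, n_tv_steps = 20L,
                               n_iterations = 30L, nonneg = TRUE) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (lam_tv <= 0) stop("lam_tv must be > 0")
  n_tv_steps <- as.integer(n_tv_steps)
  if (n_tv_steps < 0) stop("n_tv_steps must be >= 0")
  sp <- sart_params(lam = lam, lam_red = lam_red, n_iterations = 1L,
                    nonneg = nonneg)
  structure(list(lam = sp$lam, lam_red = sp$lam_red, alpha = alpha,
                 lam_tv = lam_tv, n_tv_steps = n_tv_steps,
                 n_iterations = as.integer(n_iterations),
                 nonneg = sp$nonneg),
            class = "tv_baseline_params")
}

# smoothed isotropic total variation and its gradient (compiled kernels;
# periodic boundaries, matching grad_vol)
smoothed_tv <- function(values, delta = 1e-8) {
  cpp_smoothed_tv(values, dim(values), delta)
}

smoothed_tv_grad <- function(values, delta = 1e-8) {
  array(cpp_smoothed_tv_grad(values, dim(values), delta), dim = dim(values))
}

#' Steepest descent on smoothed total variation
#'
#' Performs `n_steps` normalized steepest-descent steps on the smoothed
#' isotropic TV `sum sqrt(|grad x|^2 + delta^2)`.  Each step moves the image
#' by at most `step_size` (in image 2-norm); backtracking halves the step
#' until the smoothed TV does not increase, so the descent contract
#' `TV(out) <= TV(in)` always holds.
#'
#' @param volume A [ct_volume()].
#' @param n_steps Number of descent steps.
#' @param step_size Step length in image 2-norm units.
#' @param delta Smoothing constant in the TV magnitude (default `1e-8`).
#' @return The descended [ct_volume()].
#' @export
tv_gradient_descent <- function(volume, n_steps, step_size, delta = 1e-8) {
  stopifnot(inherits(volume, "ct_volume"))
  x <- volume$values
  if (n_steps < 1 || step_size <= 0) return(volume)
  tv <- smoothed_tv(x, delta)
  for (k in seq_len(n_steps)) {
    g <- smoothed_tv_grad(x, delta)
    gn <- sqrt(sum(g^2))
    if (gn == 0) break
    s <- step_size
    accepted <- FALSE
    for (bt in 1:20) {
      cand <- x - (s / gn) * g
      tv_cand <- smoothed_tv(cand, delta)
      if (tv_cand <= tv) {
        x <- cand; tv <- tv_cand; accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) break
  }
  ct_volume(volume$grid, x)
}

# shared outer loop: one SART pass then a TV stage with per-step length
# step_of_dp(dp), dp = ||data update||_2
tv_pocs_loop <- function(projections, grid, params, step_of_dp) {
  geometry <- projections$geometry
  tables <- sart_tables(geometry, grid)
  sp <- sart_params(lam = params$lam, lam_red = params$lam_red,
                    n_iterations = 1L, nonneg = params$nonneg)
  x <- ct_volume(grid, 0)
  lam <- params$lam
  hist <- data.frame(iteration = integer(), residual_norm = numeric(),
                     tv = numeric())
  for (k in seq_len(params$n_iterations)) {
    x_prev <- x$values
    x <- sart_reconstruct(projections, grid, sp, initial = x,
                          tables = tables, lam0 = lam,
                          track_residual = FALSE)
    lam <- attr(x, "final_lam")
    dp <- sqrt(sum((x$values - x_prev)^2))
    step <- step_of_dp(dp)
    if (params$n_tv_steps > 0 && step > 0 && dp > 0)
      x <- tv_gradient_descent(x, params$n_tv_steps, step)
    hist <- rbind(hist, data.frame(iteration = k, residual_norm = NA_real_,
                                   tv = smoothed_tv(x$values)))
  }
  attr(x, "history") <- hist
  x
}

#' ASD-POCS reconstruction
#'
#' Adaptive steepest-descent projection-onto-convex-sets: alternates a SART
#' data-consistency pass (with nonnegativity) and TV steepest descent whose
#' per-step length is `alpha` times the magnitude of the preceding data
#' update, the adaptive coupling of the Sidky-Pan construction.
#'
#' @param projections A [projection_set()].
#' @param grid Reconstruction [volume_grid()].
#' @param params A [tv_baseline_params()].
#' @return A [ct_volume()] with a per-iteration `"history"` attribute.
#' @export
asd_pocs_reconstruct <- function(projections, grid,
                                 params = tv_baseline_params()) {
  stopifnot(inherits(params, "tv_baseline_params"))
  if (length(projections$frames) == 0) stop("empty projections")
  tv_pocs_loop(projections, grid, params,
               step_of_dp = function(dp) params$alpha * dp)
}

#' SART-TV reconstruction
#'
#' Each outer iteration runs one SART pass followed by `n_tv_steps` TV
#' steepest-descent steps whose step length is `n_tv_steps / lam_tv` times
#' the data-update magnitude.  `lam_tv` is the ratio of importance of the
#' image (data fidelity) versus the minimum total variation: small values
#' smooth aggressively, `lam_tv = Inf` degenerates to plain SART.
#'
#' @inheritParams asd_pocs_reconstruct
#' @return A [ct_volume()] with a per-iteration `"history"` attribute.
#' @export
sart_tv_reconstruct <- function(projections, grid,
                                params = tv_baseline_params()) {
  stopifnot(inherits(params, "tv_baseline_params"))
  if (length(projections$frames) == 0) stop("empty projections")
  tv_pocs_loop(projections, grid, params,
               step_of_dp = function(dp) {
                 if (is.infinite(params$lam_tv)) 0
                 else params$n_tv_steps / params$lam_tv * dp
               })
}
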