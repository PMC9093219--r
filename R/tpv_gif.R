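#' Parameters for guided-filter fused reconstruction
#'
#' @param n_outer Total outer iterations `N` (each runs one SART pass and
#'   one guided filtering of the result; default 10, tuned on the built-in
#'   head phantom).
#' @param sart A [sart_params()] for the per-iteration SART pass; its
#'   `n_iterations` is forced to 1 (one full pass per outer iteration) and
#'   its relaxation keeps decaying by `lam_red` across outer iterations.
#' @param tpv A [tpv_params()] for the initial-guidance reconstruction.
#' @param gif A [guided_filter_params()], or `NULL` for a pass-through
#'   filter (no smoothing; useful for composition checks).
#' @return An object of class `tpv_gif_params`.
#' @export
tpv_gif_params <- function(n_outer = 10L, sart = sart_params(),
                           tpv = tpv_params(), gif = guided_filter_params()) {
  n_outer <- as.integer(n_outer)
  if (n_outer < 1) stop("n_outer must be >= 1")
  stopifnot(inherits(sart, "sart_params"), inherits(tpv, "tpv_params"))
  if (!is.null(gif)) stopifnot(inherits(gif, "guided_filter_params"))
  sart$n_iterations <- 1L
  structure(list(n_outer = n_outer, sart = sart, tpv = tpv, gif = gif),
            class = "tpv_gif_params")
}

#' Guidance-image schedule
#'
#' Voxelwise convex combination phasing the initial (TpV) guidance out in
#' favour of the evolving SART result:
#' `I_guide = I_initial * (N - n)/N + f_sart * n/N`.  At `n = N` the initial
#' guidance has been fully phased out.
#'
#' @param initial_guidance The initial guidance volume (a [ct_volume()]).
#' @param sart_result The current SART pass result, same grid.
#' @param n Outer iteration index, `1 <= n <= N`.
#' @param N Total outer iterations.
#' @return The blended guidance [ct_volume()].
#' @export
update_guidance <- function(initial_guidance, sart_result, n, N) {
  stopifnot(inherits(initial_guidance, "ct_volume"),
            inherits(sart_result, "ct_volume"))
  if (!grid_equal(initial_guidance$grid, sart_result$grid))
    stop("guidance volumes must share one grid")
  n <- as.integer(n); N <- as.integer(N)
  if (!(n >= 1 && n <= N)) stop("need 1 <= n <= N")
  w <- (N - n) / N
  ct_volume(initial_guidance$grid,
            initial_guidance$values * w + sart_result$values * (1 - w))
}

#' Guided-filter fused TpV/SART reconstruction
#'
#' The shipped method: a TpV reconstruction provides the initial guidance
#' image; each of `N` outer iterations then (i) runs one SART pass from the
#' previous estimate, (ii) blends the guidance by [update_guidance()], and
#' (iii) guided-filters the SART result (slice by slice, jointly min-max
#' normalized with its guide) under that guidance.  Early iterations inherit
#' TpV's noise suppression; late iterations keep SART's edge detail.
#'
#' @param projections A [projection_set()].
#' @param grid Reconstruction [volume_grid()].
#' @param params A [tpv_gif_params()].
#' @param initial Starting volume `f^(0)` (default zero).
#' @param initial_guidance Optional precomputed TpV volume to use as
#'   `I_initial` (skips the internal TpV solve; must equal
#'   `tpv_reconstruct(projections, grid, params$tpv)` for the algorithm as
#'   published).
#' @return A nonnegative [ct_volume()]; attribute `"history"` records the
#'   per-outer-iteration guidance weight, and `"initial_guidance"` the TpV
#'   volume used as `I_initial`.
#' @export
tpv_gif_reconstruct <- function(projections, grid,
                                params = tpv_gif_params(), initial = NULL,
                                initial_guidance = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"),
            inherits(params, "tpv_gif_params"))
  if (length(projections$frames) == 0) stop("empty projections")
  geometry <- projections$geometry
  i_init <- if (is.null(initial_guidance)) {
    tpv_reconstruct(projections, grid, params$tpv)
  } else {
    stopifnot(inherits(initial_guidance, "ct_volume"))
    if (!grid_equal(initial_guidance$grid, grid))
      stop("initial_guidance grid mismatch")
    initial_guidance
  }
  tables <- sart_tables(geometry, grid)
  f <- if (is.null(initial)) ct_volume(grid, 0) else initial
  stopifnot(inherits(f, "ct_volume"))
  if (!grid_equal(f$grid, grid)) stop("initial volume grid mismatch")
  lam <- params$sart$lam
  N <- params$n_outer
  hist <- data.frame(iteration = integer(), guidance_weight = numeric(),
                     lam = numeric())
  for (n in seq_len(N)) {
    f_sart <- sart_reconstruct(projections, grid, params$sart, initial = f,
                               tables = tables, lam0 = lam,
                               track_residual = FALSE)
    lam <- attr(f_sart, "final_lam")
    guide <- update_guidance(i_init, f_sart, n, N)
    f <- if (is.null(params$gif)) {
      f_sart
    } else {
      guided_filter_volume(guide, f_sart, params$gif, normalize = TRUE)
    }
    f <- ct_volume(grid, pmax(f$values, 0))
    hist <- rbind(hist, data.frame(iteration = n,
                                   guidance_weight = (N - n) / N,
                                   lam = lam))
  }
  attr(f, "history") <- hist
  attr(f, "initial_guidance") <- i_init
  f
}
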