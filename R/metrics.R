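as_values <- function(x) {
  if (inherits(x, "ct_volume")) x$values else as.array(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes must have the same shape")
}

#' Root-mean-square error between volumes
#'
#' `sqrt(mean((recon - reference)^2))` over all voxels.
#'
#' @param recon,reference Volumes ([ct_volume()] or arrays) of equal shape.
#' @return The RMSE (intensity units).
#' @export
rmse <- function(recon, reference) {
  a <- as_values(recon); b <- as_values(reference)
  check_same_shape(a, b)
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10((2^l - 1)^2 / MSE)` in dB, with `l` the bit depth of the
#' intensity range; for unit-range images (`l = 1`, the default) this is
#' `10 log10(1 / MSE)`.  Identical volumes give `Inf`.
#'
#' @inheritParams rmse
#' @param l Bit depth of the intensity range (1 for `[0, 1]` images).
#' @return PSNR in dB.
#' @export
psnr <- function(recon, reference, l = 1) {
  a <- as_values(recon); b <- as_values(reference)
  check_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  peak <- 2^l - 1
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (global statistics)
#'
#' SSIM computed from the global means, variances and covariance of the two
#' volumes, with stabilizers `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`,
#' `L = 2^l - 1`.  A windowed variant averaging local SSIM over
#' `(2 radius + 1)^2` neighbourhoods of each axial slice is available via
#' `window_radius`.
#'
#' @inheritParams psnr
#' @param window_radius `NULL` (default) for global statistics, or a
#'   positive integer radius for the sliding-window mean SSIM.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(recon, reference, l = 1, window_radius = NULL) {
  a <- as_values(recon); b <- as_values(reference)
  check_same_shape(a, b)
  peak <- 2^l - 1
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  ssim_stat <- function(mua, mub, vara, varb, covab) {
    ((2 * mua * mub + c1) * (2 * covab + c2)) /
      ((mua^2 + mub^2 + c1) * (vara + varb + c2))
  }
  if (is.null(window_radius)) {
    mua <- mean(a); mub <- mean(b)
    vara <- mean((a - mua)^2); varb <- mean((b - mub)^2)
    covab <- mean((a - mua) * (b - mub))
    return(ssim_stat(mua, mub, vara, varb, covab))
  }
  r <- as.integer(window_radius)
  if (r < 1) stop("window_radius must be >= 1")
  if (length(dim(a)) == 2) { dim(a) <- c(dim(a), 1); dim(b) <- dim(a) }
  vals <- vapply(seq_len(dim(a)[3]), function(s) {
    as_ <- a[, , s]; bs <- b[, , s]
    mua <- box_mean(as_, r); mub <- box_mean(bs, r)
    vara <- box_mean(as_ * as_, r) - mua^2
    varb <- box_mean(bs * bs, r) - mub^2
    covab <- box_mean(as_ * bs, r) - mua * mub
    mean(ssim_stat(mua, mub, vara, varb, covab))
  }, numeric(1))
  mean(vals)
}

#' Voxelwise absolute difference map
#'
#' @inheritParams rmse
#' @return A [ct_volume()] (when `recon` is one) or array of `|recon -
#'   reference|`.
#' @export
abs_diff <- function(recon, reference) {
  a <- as_values(recon); b <- as_values(reference)
  check_same_shape(a, b)
  d <- abs(a - b)
  if (inherits(recon, "ct_volume")) ct_volume(recon$grid, d) else d
}

#' Extract a profile line through a volume
#'
#' Pulls one row or column of one slice: the classical profile-curve display
#' plots voxel value against position along the line for a reconstruction
#' and its reference.
#'
#' @param volume A [ct_volume()] or 3D array.
#' @param slice_axis Axis the slice is taken across: 1, 2 or 3 (default 3,
#'   axial).
#' @param slice_index Slice index along `slice_axis`.
#' @param line `"row"` (values along the slice's first in-plane axis vary)
#'   or `"col"`.
#' @param line_index Index of the fixed in-plane coordinate.
#' @return A data frame with `position` (voxel index along the line) and
#'   `value`.
#' @export
profile_line <- function(volume, slice_axis = 3L, slice_index,
                         line = c("row", "col"), line_index) {
  line <- match.arg(line)
  a <- as_values(volume)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  if (slice_index < 1 || slice_index > dim(a)[slice_axis])
    stop("slice index out of range")
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[slice_axis]] <- slice_index
  sl <- as.matrix(do.call(`[`, c(list(a), idx, list(drop = TRUE))))
  if (line == "row") {
    if (line_index < 1 || line_index > ncol(sl)) stop("line index out of range")
    v <- sl[, line_index]
  } else {
    if (line_index < 1 || line_index > nrow(sl)) stop("line index out of range")
    v <- sl[line_index, ]
  }
  data.frame(position = seq_along(v), value = as.numeric(v))
}

#' Full quality report for a reconstruction
#'
#' @inheritParams psnr
#' @return An object of class `metrics_report` with `rmse`, `psnr`, `ssim`
#'   and `bit_depth_l`.
#' @export
metrics_report <- function(recon, reference, l = 1) {
  structure(list(rmse = rmse(recon, reference),
                 psnr = psnr(recon, reference, l),
                 ssim = ssim(recon, reference, l),
                 bit_depth_l = l),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RMSE %.6g   PSNR %.4f dB   SSIM %.6f   (l = %g)\n",
              x$rmse, x$psnr, x$ssim, x$bit_depth_l))
  invisible(x)
}
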