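#' Guided-filter parameters
#'
#' @param radius Window radius `R` in pixels (window side `2R + 1`).
#' @param epsilon Regularization `eps` in squared intensity units on images
#'   scaled to `[0, 1]`; the shipped default `0.0016 = 0.04^2` is the
#'   canonical choice for unit-range images.
#' @return An object of class `guided_filter_params`.
#' @export
guided_filter_params <- function(radius = 4L, epsilon = 0.0016) {
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  if (!is.numeric(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  structure(list(radius = radius, epsilon = as.numeric(epsilon)),
            class = "guided_filter_params")
}

# windowed column sums and valid-pixel counts along dim 1
box_sum_1d <- function(m, radius) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + radius, n)
  lo <- pmax(seq_len(n) - radius, 1)
  cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
}

#' Box mean with truncated borders
#'
#' Each output pixel is the arithmetic mean of the input over the
#' `(2R+1) x (2R+1)` window centred on it, truncated to valid pixels at the
#' image border (so a constant image maps to itself exactly, borders
#' included).
#'
#' @param image A numeric matrix.
#' @param radius Window radius `R >= 1`.
#' @return A matrix of windowed means, same shape as `image`.
#' @export
box_mean <- function(image, radius) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a non-empty matrix")
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  n1 <- nrow(image); n2 <- ncol(image)
  cnt1 <- pmin(seq_len(n1) + radius, n1) - pmax(seq_len(n1) - radius, 1) + 1
  cnt2 <- pmin(seq_len(n2) + radius, n2) - pmax(seq_len(n2) - radius, 1) + 1
  s <- t(box_sum_1d(t(box_sum_1d(image, radius)), radius))
  s / outer(cnt1, cnt2)
}

#' Guided image filtering of a 2D image
#'
#' Edge-preserving filter fitting the local linear model `Q = a I + b` per
#' window: with window means from [box_mean()],
#' `a = cov_IP / (var_I + eps)`, `b = mean_P - a mean_I`, and
#' `Q = mean_a * I + mean_b`.  Structure present in the guide `I` is
#' transferred to the filtered input `P` while noise in `P` is smoothed.
#'
#' @param guide Guide image `I` (numeric matrix).
#' @param input Input image `P`, same shape as `guide`.
#' @param params A [guided_filter_params()].
#' @return The filtered image `Q`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' identical_out <- guided_filter_2d(img, img, guided_filter_params(2, 0))
#' max(abs(identical_out - img))  # identity when I = P and eps = 0
#' @export
guided_filter_2d <- function(guide, input, params = guided_filter_params()) {
  stopifnot(inherits(params, "guided_filter_params"))
  if (!is.matrix(guide) || !is.matrix(input) ||
      !identical(dim(guide), dim(input)))
    stop("guide and input must be matrices of the same shape")
  if (any(!is.finite(guide)) || any(!is.finite(input)))
    stop("images must be finite")
  r <- params$radius; eps <- params$epsilon
  mean_i <- box_mean(guide, r)
  mean_p <- box_mean(input, r)
  corr_i <- box_mean(guide * guide, r)
  corr_ip <- box_mean(guide * input, r)
  var_i <- corr_i - mean_i * mean_i
  cov_ip <- corr_ip - mean_i * mean_p
  a <- cov_ip / (var_i + eps)
  b <- mean_p - a * mean_i
  box_mean(a, r) * guide + box_mean(b, r)
}

#' Slice-wise guided filtering of a volume
#'
#' Applies [guided_filter_2d()] independently to each slice along `axis`
#' (default axial, the third array dimension).  With `normalize = TRUE` the
#' guide/input pair is jointly min-max scaled to `[0, 1]` before filtering
#' and rescaled after, so `epsilon` keeps its unit-range interpretation for
#' volumes on arbitrary intensity scales.
#'
#' @param guide_vol Guide volume (a [ct_volume()]).
#' @param input_vol Input volume on the same grid.
#' @param params A [guided_filter_params()].
#' @param axis Slice axis, 1--3 (default 3 = axial z).
#' @param normalize Jointly rescale the pair to `[0, 1]` around the filter.
#' @return A [ct_volume()] with the filtered values.
#' @export
guided_filter_volume <- function(guide_vol, input_vol,
                                 params = guided_filter_params(),
                                 axis = 3L, normalize = FALSE) {
  stopifnot(inherits(guide_vol, "ct_volume"), inherits(input_vol, "ct_volume"))
  if (!grid_equal(guide_vol$grid, input_vol$grid))
    stop("guide and input volumes must share one grid")
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  g <- guide_vol$values; p <- input_vol$values
  lo <- 0; span <- 1
  if (normalize) {
    lo <- min(g, p); hi <- max(g, p)
    span <- if (hi > lo) hi - lo else 1
    g <- (g - lo) / span; p <- (p - lo) / span
  }
  out <- array(0, dim = dim(p))
  idx <- vector("list", 3); for (a in 1:3) idx[[a]] <- quote(expr = )
  for (s in seq_len(dim(p)[axis])) {
    take <- idx; take[[axis]] <- s
    gs <- do.call(`[`, c(list(g), take, list(drop = TRUE)))
    ps <- do.call(`[`, c(list(p), take, list(drop = TRUE)))
    qs <- guided_filter_2d(as.matrix(gs), as.matrix(ps), params)
    out <- do.call(`[<-`, c(list(out), take, list(qs)))
  }
  if (normalize) out <- out * span + lo
  ct_volume(input_vol$grid, out)
}
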