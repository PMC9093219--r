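# Shared small fixtures and independent oracles.  Everything here is
# deliberately written with different algorithms/code paths than the package
# internals it checks.

small_geometry <- function(n_views = 8, det = c(24, 24), pitch = c(2.2, 2.2),
                           angles = NULL) {
  cone_beam_geometry(80, 40, n_views = n_views, view_angles = angles,
                     detector_shape = det, detector_pixel = pitch)
}

small_grid <- function(n = 16, s = 1) volume_grid(c(n, n, n), rep(s, 3))

demo_geometry <- function(n_views = 32) {
  cone_beam_geometry(1040, 570, n_views = n_views,
                     detector_shape = c(128, 128),
                     detector_pixel = c(1.6272, 1.6272))
}

demo_grid <- function() volume_grid(c(64, 64, 64), c(1, 1, 1))

# world endpoints of the ray for (view, row, col), replicated from the
# documented geometry convention
ray_endpoints <- function(geometry, view, row, col) {
  th <- geometry$view_angles[view]
  dso <- geometry$dist_source_origin
  ddo <- geometry$dist_source_detector - dso
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  du <- geometry$detector_pixel[1]; dv <- geometry$detector_pixel[2]
  u0 <- geometry$detector_offset[1]; v0 <- geometry$detector_offset[2]
  uhat <- c(-sin(th), cos(th), 0)
  src <- c(dso * cos(th), dso * sin(th), 0)
  det <- c(-ddo * cos(th), -ddo * sin(th), 0) +
    (u0 + (col - 1 - (nc - 1) / 2) * du) * uhat +
    c(0, 0, v0 + (row - 1 - (nr - 1) / 2) * dv)
  list(src = src, det = det)
}

# Independent Siddon oracle: collect the parametric positions of ALL voxel
# plane crossings along the segment, sort them, and classify each
# sub-segment by its midpoint.  No incremental traversal involved.
oracle_trace <- function(grid, src, det) {
  lo <- grid$origin - grid$shape * grid$voxel_size / 2
  hi <- lo + grid$shape * grid$voxel_size
  w <- det - src
  tmin <- 0; tmax <- 1
  for (a in 1:3) {
    if (w[a] == 0) {
      if (src[a] <= lo[a] || src[a] >= hi[a])
        return(list(voxel_indices = integer(), lengths = numeric()))
    } else {
      tt <- sort(c((lo[a] - src[a]) / w[a], (hi[a] - src[a]) / w[a]))
      tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
    }
  }
  if (tmin >= tmax)
    return(list(voxel_indices = integer(), lengths = numeric()))
  ts <- c(tmin, tmax)
  for (a in 1:3) {
    if (w[a] != 0) {
      planes <- lo[a] + (0:grid$shape[a]) * grid$voxel_size[a]
      tp <- (planes - src[a]) / w[a]
      ts <- c(ts, tp[tp > tmin & tp < tmax])
    }
  }
  ts <- sort(unique(ts))
  L <- sqrt(sum(w^2))
  js <- integer(); lens <- numeric()
  for (k in seq_len(length(ts) - 1)) {
    tm <- (ts[k] + ts[k + 1]) / 2
    p <- src + tm * w
    ijk <- floor((p - lo) / grid$voxel_size)
    if (all(ijk >= 0) && all(ijk < grid$shape)) {
      j <- 1 + ijk[1] + grid$shape[1] * (ijk[2] + grid$shape[2] * ijk[3])
      js <- c(js, as.integer(j))
      lens <- c(lens, (ts[k + 1] - ts[k]) * L)
    }
  }
  keep <- lens > 0
  list(voxel_indices = js[keep], lengths = lens[keep],
       chord = (tmax - tmin) * L)
}

# entry-exit chord length through the grid box, independent of any traversal
oracle_chord <- function(grid, src, det) {
  tr <- oracle_trace(grid, src, det)
  if (length(tr$lengths) == 0) 0 else tr$chord
}

# assemble the dense system matrix of a (small) geometry from trace_ray
dense_system_matrix <- function(geometry, grid) {
  nr <- geometry$detector_shape[1]; nc <- geometry$detector_shape[2]
  n_rays <- geometry$n_views * nr * nc
  A <- matrix(0, n_rays, prod(grid$shape))
  i <- 0
  for (v in seq_len(geometry$n_views)) {
    for (cc in seq_len(nc)) {
      for (rr in seq_len(nr)) {
        i <- i + 1
        tr <- trace_ray(geometry, grid, v, c(rr, cc))
        if (length(tr$voxel_indices) > 0)
          A[i, tr$voxel_indices] <- tr$lengths
      }
    }
  }
  A
}

# flatten a projection array in the same ray order as dense_system_matrix
flatten_frames <- function(frames) {
  as.numeric(aperm(frames, c(1, 2, 3)))
}

# Literal transcription of the published guided-filter steps with its own
# nested-loop truncated box mean.
oracle_box_mean <- function(img, r) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      i1 <- max(1, i - r); i2 <- min(n1, i + r)
      j1 <- max(1, j - r); j2 <- min(n2, j + r)
      out[i, j] <- mean(img[i1:i2, j1:j2])
    }
  }
  out
}

oracle_guided_filter <- function(I, P, r, eps) {
  mean_i <- oracle_box_mean(I, r)
  mean_p <- oracle_box_mean(P, r)
  corr_i <- oracle_box_mean(I * I, r)
  corr_ip <- oracle_box_mean(I * P, r)
  var_i <- corr_i - mean_i * mean_i
  cov_ip <- corr_ip - mean_i * mean_p
  a <- cov_ip / (var_i + eps)
  b <- mean_p - a * mean_i
  oracle_box_mean(a, r) * I + oracle_box_mean(b, r)
}

# 1-D proximal oracle for the l_p shrinkage surrogate:
# argmin_u 0.5 * beta * (u - t)^2 + u^p over u >= 0, by dense grid search
# plus golden-section refinement.
oracle_prox_lp <- function(t, beta, p) {
  f <- function(u) 0.5 * beta * (u - t)^2 + ifelse(u > 0, u^p, 0)
  us <- seq(0, t * 1.5 + 1, length.out = 20001)
  u0 <- us[which.min(f(us))]
  lo <- max(0, u0 - 2e-4 * (t + 1)); hi <- u0 + 2e-4 * (t + 1)
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-12)
  if (f(0) <= opt$objective) 0 else opt$minimum
}

# Independently written TV (p = 1) alternating-direction solver: same
# splitting, classical isotropic soft thresholding, own shift/gradient code.
oracle_tv_adm <- function(projections, grid, beta1, beta2, eta, tau, n_iter) {
  shp <- grid$shape
  fwd <- function(x, a) {
    idx <- c(seq_len(shp[a])[-1], 1)
    switch(a, x[idx, , ], x[, idx, ], x[, , idx]) - x
  }
  adj <- function(z, a) {
    idx <- c(shp[a], seq_len(shp[a] - 1))
    switch(a, z[idx, , ], z[, idx, ], z[, , idx]) - z
  }
  geom <- projections$geometry
  y <- projections$frames
  x <- array(0, dim = shp)
  z <- lapply(1:3, function(a) array(0, dim = shp))
  l1 <- lapply(1:3, function(a) array(0, dim = shp))
  l2 <- array(0, dim = dim(y))
  lam1d <- function(n) 2 - 2 * cos(2 * pi * (0:(n - 1)) / n)
  Lam <- outer(outer(lam1d(shp[1]), lam1d(shp[2]), "+"), lam1d(shp[3]), "+")
  J <- beta1 * Lam + beta2 * tau
  ax <- forward_project(ct_volume(grid, x), geom, check_fov = FALSE)$frames
  for (k in seq_len(n_iter)) {
    # z: isotropic soft threshold of grad x + l1/beta1 at 1/beta1
    v <- lapply(1:3, function(a) fwd(x, a) + l1[[a]] / beta1)
    mag <- sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
    shr <- pmax(mag - 1 / beta1, 0)
    sc <- ifelse(mag > 0, shr / mag, 0)
    z <- lapply(1:3, function(a) v[[a]] * sc)
    # x: FFT solve of the linearized normal equations
    comb <- l2 + beta2 * (ax - y)
    bp <- back_project(projection_set(geom, comb), grid)$values
    rhs <- Reduce(`+`, lapply(1:3, function(a)
      adj(beta1 * z[[a]] - l1[[a]], a))) + beta2 * tau * x - bp
    x <- pmax(Re(stats::fft(stats::fft(rhs) / J, inverse = TRUE)) /
                prod(shp), 0)
    ax <- forward_project(ct_volume(grid, x), geom, check_fov = FALSE)$frames
    # e = 0 (eps_data = 0), multipliers
    for (a in 1:3) l1[[a]] <- l1[[a]] - eta * beta1 * (z[[a]] - fwd(x, a))
    l2 <- l2 - eta * beta2 * (y - ax)
  }
  x
}

# one-ellipsoid ball phantom centred at the isocenter
ball_phantom <- function(grid, radius_frac = 0.6) {
  half <- min(grid$shape * grid$voxel_size) / 2
  make_phantom(list(ellipsoid_spec(c(0, 0, 0), rep(half * radius_frac, 3),
                                   value_delta = 1)), grid)
}
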