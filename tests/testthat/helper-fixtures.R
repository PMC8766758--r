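# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms from the package internals (ray casting, raster
# scans, brute-force sweeps).

tiny_apertures <- function(field_radius = 8, grid_n = 41,
                           kinds = c("wedge", "bar")) {
  lapply(kinds, function(k) {
    make_aperture(k, field_radius = field_radius, grid_n = grid_n)
  })
}

tiny_search <- function(field_radius = 8, n_xy = 9,
                        sigmas = c(0.5, 1, 2)) {
  prf_search_grid(field_radius, n_xy = n_xy, sigmas = sigmas)
}

# ray-casting point-in-polygon (boundary not handled specially; callers
# keep probes away from edges)
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# rasterization oracle: does the disc share any raster point with the hull?
oracle_circle_hull <- function(center, radius, hull, step = 0.02) {
  v <- hull$vertices
  lo <- pmax(apply(v, 2, min), center - radius) - step
  hi <- pmin(apply(v, 2, max), center + radius) + step
  if (any(lo > hi)) return(FALSE)
  xs <- seq(lo[1], hi[1], by = step)
  ys <- seq(lo[2], hi[2], by = step)
  g <- expand.grid(x = xs, y = ys)
  # the disc center itself is always a valid probe (covers discs smaller
  # than one raster cell)
  g <- rbind(g, data.frame(x = center[1], y = center[2]))
  in_disc <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  if (!any(in_disc)) return(FALSE)
  if (nrow(v) >= 3) {
    any(oracle_in_polygon(g$x[in_disc], g$y[in_disc], v[, 1], v[, 2]))
  } else {
    # degenerate hull: sample points along the point/segment
    if (nrow(v) == 1) {
      sum((v[1, ] - center)^2) <= radius^2
    } else {
      t <- seq(0, 1, length.out = 2001)
      px <- v[1, 1] + t * (v[2, 1] - v[1, 1])
      py <- v[1, 2] + t * (v[2, 2] - v[1, 2])
      any((px - center[1])^2 + (py - center[2])^2 <= radius^2)
    }
  }
}

# rasterized hull area at a given resolution
oracle_hull_area <- function(hull, step = 0.05) {
  v <- hull$vertices
  lo <- apply(v, 2, min) - step
  hi <- apply(v, 2, max) + step
  g <- expand.grid(x = seq(lo[1], hi[1], by = step),
                   y = seq(lo[2], hi[2], by = step))
  sum(oracle_in_polygon(g$x, g$y, v[, 1], v[, 2])) * step^2
}

# brute-force two-sample KS statistic: sweep every pooled value
oracle_ks_d <- function(x, y) {
  ts <- c(x, y)
  max(vapply(ts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# 3D rotation matrix from an axis and angle
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# minimal hand-built fits table for geometry/counting tests
toy_fits <- function(x0, y0, sigma, r2 = 0.9, roi = "V1d",
                     hemisphere = "lesioned") {
  n <- length(x0)
  data.frame(voxel = seq_len(n), x0 = x0, y0 = y0,
             sigma = rep_len(sigma, n), amplitude = rep_len(1, n),
             r2 = rep_len(r2, n), degenerate = rep_len(FALSE, n),
             roi = rep_len(roi, n), hemisphere = rep_len(hemisphere, n))
}
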