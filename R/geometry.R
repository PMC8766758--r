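# Internal planar geometry helpers shared by the perimetry and
# residual-function modules. Hulls are stored as CCW vertex matrices;
# degenerate hulls (a single point or a collinear segment) are supported
# throughout.

# signed area via the shoelace formula (positive = counter-clockwise)
signed_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(v) {
  if (signed_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

# minimum distance from each point (rows of p) to segment a-b
dist_points_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  dx <- p[, 1] - a[1]
  dy <- p[, 2] - a[2]
  if (len2 == 0) return(sqrt(dx^2 + dy^2))
  t <- pmin(pmax((dx * ab[1] + dy * ab[2]) / len2, 0), 1)
  sqrt((dx - t * ab[1])^2 + (dy - t * ab[2])^2)
}

# minimum distance from points to the boundary of a vertex chain
dist_points_boundary <- function(p, v) {
  n <- nrow(v)
  if (n == 1) {
    return(sqrt((p[, 1] - v[1, 1])^2 + (p[, 2] - v[1, 2])^2))
  }
  d <- rep(Inf, nrow(p))
  idx <- cbind(seq_len(n), c(2:n, 1))
  if (n == 2) idx <- idx[1, , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    d <- pmin(d, dist_points_segment(p, v[idx[r, 1], ], v[idx[r, 2], ]))
  }
  d
}

# are points inside (or on the boundary of) a CCW convex polygon?
points_in_convex <- function(p, v, eps = 1e-12) {
  n <- nrow(v)
  if (n < 3) return(dist_points_boundary(p, v) <= eps)
  inside <- rep(TRUE, nrow(p))
  j <- c(2:n, 1)
  for (i in seq_len(n)) {
    ex <- v[j[i], 1] - v[i, 1]
    ey <- v[j[i], 2] - v[i, 2]
    cr <- ex * (p[, 2] - v[i, 2]) - ey * (p[, 1] - v[i, 1])
    inside <- inside & cr >= -eps
  }
  inside
}

# point-in-polygon (general simple polygon, boundary-inclusive) by crossing
# count plus a boundary-distance check; used for synthetic scotoma regions
points_in_polygon <- function(p, v, eps = 1e-9) {
  n <- nrow(v)
  if (n < 3) return(dist_points_boundary(p, v) <= eps)
  inside <- rep(FALSE, nrow(p))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > p[, 2]) != (yj > p[, 2])) &
      (p[, 1] < (xj - xi) * (p[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | dist_points_boundary(p, v) <= eps
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, 1:2])
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  storage.mode(p) <- "double"
  p
}
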