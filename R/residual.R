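#' Mirror-flip a scotoma hull across the vertical meridian
#'
#' Reflects the blind region into the intact hemifield (every vertex
#' `(x, y) -> (-x, y)`), giving the control region against which pRF counts
#' from the non-lesioned hemisphere are measured. Orientation is
#' re-normalized to counter-clockwise; the reflection is an isometry, so the
#' area is preserved exactly.
#'
#' @param hull A [scotoma_hull()].
#' @return The reflected `scotoma_hull`.
#' @export
mirror_flip <- function(hull) {
  stopifnot(inherits(hull, "scotoma_hull"))
  if (hull$empty) return(hull)
  v <- hull$vertices
  v[, 1] <- -v[, 1]
  p <- hull$points
  p[, 1] <- -p[, 1]
  hull$vertices <- ensure_ccw(v)
  hull$points <- p
  hull
}

#' Does a pRF disc intersect the scotoma hull?
#'
#' Each pRF is approximated as a closed disc in visual space centered at its
#' fitted position with radius sigma. The disc intersects the (closed) hull
#' iff the center lies inside the hull or the distance from the center to the
#' hull boundary does not exceed the radius; tangency therefore counts as
#' intersection. Degenerate hulls (point/segment) use point/segment distance;
#' the empty-scotoma sentinel intersects nothing.
#'
#' @param center Numeric pair (x, y) in degrees, or a matrix/data frame of
#'   centers (one per row).
#' @param radius Disc radius (degrees), scalar or one per center; must be
#'   non-negative.
#' @param hull A [scotoma_hull()].
#' @return Logical, one value per center.
#' @export
circle_intersects_hull <- function(center, radius, hull) {
  stopifnot(inherits(hull, "scotoma_hull"))
  p <- as_point_matrix(center)
  if (any(radius < 0)) stop("radius must be non-negative")
  radius <- rep_len(radius, nrow(p))
  if (hull$empty) return(rep(FALSE, nrow(p)))
  v <- hull$vertices
  near <- dist_points_boundary(p, v) <= radius
  if (nrow(v) >= 3) near | points_in_convex(p, v) else near
}

#' Replicate native fits into unit standard-space voxels
#'
#' Functional voxels are acquired on a coarse grid (3 mm here) but counts are
#' reported in 1 mm standard-space units: each native voxel is replicated
#' into `factor^3` unit voxels with no interpolation, so the native fit stays
#' authoritative and counts have units of mm^3. The native voxel identity is
#' recoverable from every replicate.
#'
#' @param fits A `prf_fits` data frame (typically with `roi` and `hemisphere`
#'   columns attached).
#' @param factor Linear supersampling factor (default 3, i.e. 27 unit voxels
#'   per native voxel).
#' @return The fits replicated `factor^3` times, with columns `native_voxel`
#'   and `replicate`.
#' @export
supersample_fits <- function(fits, factor = 3) {
  stopifnot(factor >= 1, factor == round(factor))
  n_rep <- as.integer(factor)^3
  idx <- rep(seq_len(nrow(fits)), each = n_rep)
  out <- fits[idx, , drop = FALSE]
  out$native_voxel <- fits$voxel[idx]
  out$replicate <- rep(seq_len(n_rep), nrow(fits))
  rownames(out) <- NULL
  out
}

#' Count pRFs intersecting the scotoma
#'
#' Number of supersampled (1 mm) voxels whose fit is reliable
#' (`r2 >= threshold`) and whose pRF disc (radius = fitted sigma) intersects
#' the scotoma hull. With the default 3 mm -> 1 mm replication the count is
#' expressed in mm^3 of cortex.
#'
#' @param fits Supersampled fits (see [supersample_fits()]); native fits are
#'   accepted too, in which case each row counts once.
#' @param hull A [scotoma_hull()]; for the non-lesioned hemisphere pass the
#'   [mirror_flip()]ed hull.
#' @param threshold Reliability threshold on r2.
#' @return Integer count, with attribute `status` set to `"empty_scotoma"`
#'   when the hull is the empty sentinel (count 0).
#' @export
count_scotoma_prfs <- function(fits, hull, threshold) {
  stopifnot(inherits(hull, "scotoma_hull"))
  if (hull$empty) {
    return(structure(0L, status = "empty_scotoma"))
  }
  keep <- !is.na(fits$r2) & fits$r2 >= threshold & !fits$degenerate
  if (!any(keep)) return(structure(0L, status = "ok"))
  f <- fits[keep, , drop = FALSE]
  hit <- circle_intersects_hull(cbind(f$x0, f$y0), f$sigma, hull)
  structure(as.integer(sum(hit)), status = "ok")
}

#' Visual field coverage map for a set of pRFs
#'
#' Summarizes where in the visual field a region's voxels respond: the value
#' at each field location is the maximum over fits of the voxel's Gaussian
#' profile. In `normalized` mode every profile is peak-scaled to 1 (map
#' values in [0, 1]); in `non_normalized` mode profiles are scaled by the
#' fitted amplitude and the map range runs from zero to the maximum
#' amplitude over voxels.
#'
#' @param fits A `prf_fits` data frame (usually reliable fits for one ROI);
#'   may have zero rows.
#' @param grid_x,grid_y Field-grid axes in degrees.
#' @param mode `"normalized"` or `"non_normalized"`.
#' @param combine `"max"` (default) or `"sum"` across pRFs.
#' @return An object of class `coverage_map`: list with `grid_x`, `grid_y`,
#'   `values` (matrix `length(grid_x) x length(grid_y)`), `mode`.
#' @export
coverage_map <- function(fits, grid_x = seq(-10, 10, length.out = 101),
                         grid_y = grid_x,
                         mode = c("normalized", "non_normalized"),
                         combine = c("max", "sum")) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  nx <- length(grid_x)
  ny <- length(grid_y)
  vals <- matrix(0, nx, ny)
  X <- matrix(grid_x, nx, ny)
  Y <- matrix(grid_y, nx, ny, byrow = TRUE)
  if (nrow(fits) > 0) {
    for (i in seq_len(nrow(fits))) {
      if (is.na(fits$x0[i])) next
      g <- exp(-((X - fits$x0[i])^2 + (Y - fits$y0[i])^2) /
                 (2 * fits$sigma[i]^2))
      if (mode == "non_normalized") g <- fits$amplitude[i] * g
      vals <- if (combine == "max") pmax(vals, g) else vals + g
    }
  }
  structure(list(grid_x = grid_x, grid_y = grid_y, values = vals,
                 mode = mode),
            class = "coverage_map")
}

#' Two-sample Kolmogorov-Smirnov comparison of r2 distributions
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs, evaluated by a sweep over the pooled sample; the p-value comes from
#' the asymptotic Kolmogorov distribution with effective sample size
#' `n1 n2 / (n1 + n2)`. Inputs should contain one value per uniquely
#' identified native voxel (deduplicate supersampled fits first, e.g. with
#' [unique_voxel_r2()]).
#'
#' If either sample is empty the comparison is impossible; a sentinel with
#' `status = "no_overlap"` and `NA` statistics is returned instead of an
#' error.
#'
#' @param x,y Numeric samples (e.g. r2 values from the lesioned and healthy
#'   hemisphere for one ROI).
#' @return An object of class `ks_result`: list with `D`, `p`, `n1`, `n2`,
#'   `status`.
#' @export
ks_compare <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    return(structure(list(D = NA_real_, p = NA_real_, n1 = n1, n2 = n2,
                          status = "no_overlap"),
                     class = "ks_result"))
  }
  z <- sort(unique(c(x, y)))
  e1 <- findInterval(z, sort(x)) / n1
  e2 <- findInterval(z, sort(y)) / n2
  D <- max(abs(e1 - e2))
  p <- ks_asymptotic_p(D, n1 * n2 / (n1 + n2))
  structure(list(D = D, p = p, n1 = n1, n2 = n2, status = "ok"),
            class = "ks_result")
}

# asymptotic Kolmogorov tail probability Q(sqrt(ne) * D)
ks_asymptotic_p <- function(D, ne) {
  if (D == 0) return(1)
  lambda2 <- ne * D^2
  j <- 1:200
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  if (x$status == "no_overlap") {
    cat("ks_result: no overlapping voxels (-)\n")
  } else {
    cat(sprintf("ks_result: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
                x$D, x$p, x$n1, x$n2))
  }
  invisible(x)
}

#' One r2 value per uniquely identified native voxel
#'
#' @param fits Fits, possibly supersampled; deduplicated on `native_voxel`
#'   when present (first replicate kept), otherwise on `voxel`.
#' @return Numeric vector of r2 values.
#' @export
unique_voxel_r2 <- function(fits) {
  key <- if ("native_voxel" %in% names(fits)) fits$native_voxel else fits$voxel
  fits$r2[!duplicated(key)]
}

#' Per-ROI residual-function summary
#'
#' For every atlas ROI, counts the supersampled reliable pRFs of the
#' lesioned hemisphere intersecting the scotoma hull, the matching control
#' count from the healthy hemisphere against the mirror-flipped hull, and a
#' Kolmogorov-Smirnov comparison of the r2 distributions of the unique
#' voxels overlapping each region. ROIs with no overlapping voxels on either
#' side carry the `no_overlap` sentinel.
#'
#' @param fits Native `prf_fits` with `roi` and `hemisphere`
#'   (`"lesioned"`/`"healthy"`) columns.
#' @param hull Scotoma hull from perimetry.
#' @param threshold Reliability threshold on r2.
#' @param factor Supersampling factor (see [supersample_fits()]).
#' @return Data frame with one row per ROI: `roi`, `count_mm3`,
#'   `control_count_mm3`, `D`, `p`, `n1`, `n2`, `status`.
#' @export
residual_summary <- function(fits, hull, threshold, factor = 3) {
  stopifnot(all(c("roi", "hemisphere") %in% names(fits)))
  flipped <- mirror_flip(hull)
  rois <- unique(fits$roi)
  rows <- lapply(rois, function(roi) {
    les <- fits[fits$roi == roi & fits$hemisphere == "lesioned", ,
                drop = FALSE]
    hea <- fits[fits$roi == roi & fits$hemisphere == "healthy", ,
                drop = FALSE]
    n_les <- count_scotoma_prfs(supersample_fits(les, factor), hull,
                                threshold)
    n_hea <- count_scotoma_prfs(supersample_fits(hea, factor), flipped,
                                threshold)
    ov_les <- les[!les$degenerate &
                    circle_intersects_hull(cbind(les$x0, les$y0), les$sigma,
                                           hull), , drop = FALSE]
    ov_hea <- hea[!hea$degenerate &
                    circle_intersects_hull(cbind(hea$x0, hea$y0), hea$sigma,
                                           flipped), , drop = FALSE]
    ks <- ks_compare(unique_voxel_r2(ov_les), unique_voxel_r2(ov_hea))
    data.frame(roi = roi, count_mm3 = as.integer(n_les),
               control_count_mm3 = as.integer(n_hea),
               D = ks$D, p = ks$p, n1 = ks$n1, n2 = ks$n2,
               status = ks$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
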