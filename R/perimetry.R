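#' Normative hill of vision
#'
#' Age-normal sensitivity as a function of visual field location, modeled as
#' a peak at fixation falling off linearly with eccentricity (floored at 0
#' dB). Used as the reference for the adaptive expansion rule and the mean
#' deviation. A data frame with columns `x`, `y`, `normal_db` can be used in
#' its place wherever a normative field is accepted (a tabulated hill of
#' vision, defined only at its listed locations).
#'
#' @param peak_db Sensitivity at fixation in dB.
#' @param slope_db_per_deg Linear fall-off with eccentricity in dB/degree.
#' @return An object of class `normative_field`.
#' @export
normative_field <- function(peak_db = 30, slope_db_per_deg = 0.3) {
  stopifnot(peak_db > 0, slope_db_per_deg >= 0)
  structure(list(peak_db = peak_db, slope_db_per_deg = slope_db_per_deg),
            class = "normative_field")
}

#' Evaluate a normative field at locations
#'
#' @param normals A [normative_field()] or a data frame with `x`, `y`,
#'   `normal_db`.
#' @param x,y Field locations in degrees.
#' @return Normal sensitivity in dB at each location. Tabulated normals raise
#'   an error listing any locations they do not cover.
#' @export
normal_db <- function(normals, x, y) {
  if (inherits(normals, "normative_field")) {
    return(pmax(0, normals$peak_db -
                  normals$slope_db_per_deg * sqrt(x^2 + y^2)))
  }
  stopifnot(is.data.frame(normals))
  key <- paste(round(normals$x, 6), round(normals$y, 6))
  idx <- match(paste(round(x, 6), round(y, 6)), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    stop("no normative value at location(s): ",
         paste(sprintf("(%g, %g)", x[miss], y[miss]), collapse = ", "))
  }
  normals$normal_db[idx]
}

# measured sensitivity with the configured floor for unseen points
measured_db <- function(points, floor_db = 0) {
  ifelse(points$seen, points$threshold_db, floor_db)
}

#' Spatially adaptive expansion of perimetry test points
#'
#' Perimetry with an adaptive probe retests the neighborhood of any suspect
#' defect: whenever a tested point's sensitivity falls more than 6 dB below
#' the age-normal value (strict inequality), its four grid neighbors are
#' queued for testing. Already-tested locations and locations beyond the
#' test extent are excluded.
#'
#' @param tested Data frame of tested points with columns `x`, `y`,
#'   `threshold_db`, `seen`. All points must lie on the grid.
#' @param normals Normative field (see [normal_db()]).
#' @param grid_step Grid spacing in degrees.
#' @param max_extent Maximum test eccentricity in degrees (default 50).
#' @param criterion_db Deviation criterion in dB (default 6).
#' @param floor_db Sensitivity assigned to unseen points.
#' @return Data frame with columns `x`, `y`: the new locations to test
#'   (possibly zero rows).
#' @export
adaptive_expand <- function(tested, normals, grid_step,
                            max_extent = 50, criterion_db = 6,
                            floor_db = 0) {
  stopifnot(grid_step > 0)
  gx <- tested$x / grid_step
  gy <- tested$y / grid_step
  if (any(abs(gx - round(gx)) > 1e-6) || any(abs(gy - round(gy)) > 1e-6)) {
    off <- which(abs(gx - round(gx)) > 1e-6 | abs(gy - round(gy)) > 1e-6)
    stop("tested points off the grid: ",
         paste(sprintf("(%g, %g)", tested$x[off], tested$y[off]),
               collapse = ", "))
  }
  dev <- normal_db(normals, tested$x, tested$y) - measured_db(tested, floor_db)
  flagged <- which(dev > criterion_db)
  if (length(flagged) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  nb <- do.call(rbind, lapply(flagged, function(i) {
    cbind(x = tested$x[i] + c(grid_step, -grid_step, 0, 0),
          y = tested$y[i] + c(0, 0, grid_step, -grid_step))
  }))
  nb <- as.data.frame(nb)
  nb <- unique(nb)
  tested_key <- paste(round(tested$x / grid_step), round(tested$y / grid_step))
  keep <- !(paste(round(nb$x / grid_step), round(nb$y / grid_step)) %in%
              tested_key) & sqrt(nb$x^2 + nb$y^2) <= max_extent
  out <- nb[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean deviation of a perimetry field
#'
#' Mean difference between the measured sensitivities and the age-normal hill
#' of vision over all tested points. Under the default sign convention
#' (`measured - normal`) field loss is negative. Unseen points enter at the
#' configured floor sensitivity.
#'
#' @inheritParams adaptive_expand
#' @param sign `"measured_minus_normal"` (default; loss < 0) or
#'   `"normal_minus_measured"`.
#' @return Mean deviation in dB.
#' @export
mean_deviation <- function(tested, normals,
                           sign = c("measured_minus_normal",
                                    "normal_minus_measured"),
                           floor_db = 0) {
  sign <- match.arg(sign)
  d <- measured_db(tested, floor_db) - normal_db(normals, tested$x, tested$y)
  if (sign == "normal_minus_measured") d <- -d
  mean(d)
}

#' Fixation stability: bivariate contour ellipse area
#'
#' Summarizes a cloud of fixation positions by the area of the ellipse
#' containing a stated fraction of samples under a bivariate normal model:
#' `BCEA = 2 k pi sigma_h sigma_v sqrt(1 - rho^2)` with
#' `k = -ln(1 - containment_p)`. Sample (n-1) standard deviations and the
#' Pearson correlation are used, so the requested containment fraction is
#' honored exactly for any `containment_p` rather than via a fixed constant.
#'
#' @param samples Matrix or data frame of fixation positions in degrees
#'   (columns x, y); at least 3 samples.
#' @param containment_p Fraction of fixations the ellipse should contain
#'   (default 0.63).
#' @return An object of class `fixation_stats`: list with `sigma_h`,
#'   `sigma_v`, `rho`, `bcea` (deg^2), `containment_p` and `center`.
#' @examples
#' cloud <- make_fixation_cloud(0.5, 0.5, 0, n = 1000, seed = 1)
#' bcea(cloud)$bcea
#' @export
bcea <- function(samples, containment_p = 0.63) {
  p <- as_point_matrix(samples)
  if (nrow(p) < 3) stop("need at least 3 fixation samples")
  if (containment_p <= 0 || containment_p >= 1) {
    stop("containment_p must lie in (0, 1)")
  }
  sh <- stats::sd(p[, 1])
  sv <- stats::sd(p[, 2])
  if (sh == 0 || sv == 0) {
    warning("degenerate fixation cloud (zero variance); BCEA = 0")
    rho <- 0
    area <- 0
  } else {
    rho <- stats::cor(p[, 1], p[, 2])
    if (1 - rho^2 < 1e-12) {
      warning("perfectly collinear fixation cloud; BCEA = 0")
      area <- 0
    } else {
      k <- -log(1 - containment_p)
      area <- 2 * k * pi * sh * sv * sqrt(1 - rho^2)
    }
  }
  structure(list(sigma_h = sh, sigma_v = sv, rho = rho, bcea = area,
                 containment_p = containment_p, center = colMeans(p)),
            class = "fixation_stats")
}

#' Which samples fall inside the BCEA ellipse?
#'
#' @param stats A [bcea()] result.
#' @param samples Positions to test (matrix/data frame, columns x, y).
#' @return Logical vector; `TRUE` where the sample lies inside (or on) the
#'   containment ellipse.
#' @export
bcea_contains <- function(stats, samples) {
  p <- as_point_matrix(samples)
  dx <- (p[, 1] - stats$center[1]) / stats$sigma_h
  dy <- (p[, 2] - stats$center[2]) / stats$sigma_v
  rho <- stats$rho
  d2 <- (dx^2 - 2 * rho * dx * dy + dy^2) / (1 - rho^2)
  k <- -log(1 - stats$containment_p)
  d2 <= 2 * k
}

#' Convex hull of the scotoma
#'
#' The scotoma is summarized by the convex hull of the perimetry locations
#' the participant failed to see. Degenerate cases are represented
#' explicitly: a single unseen point gives a point-hull, two or collinear
#' points a segment-hull, and an intact field (no unseen points) an empty
#' sentinel rather than an error — downstream intersection tests handle all
#' three.
#'
#' @param points Data frame of perimetry points with columns `x`, `y` and
#'   logical `seen` (or a matrix of already-unseen coordinates).
#' @return An object of class `scotoma_hull`: list with `vertices` (CCW
#'   matrix), `points` (the unseen coordinates), `empty` flag.
#' @export
scotoma_hull <- function(points) {
  if (is.data.frame(points) && "seen" %in% names(points)) {
    pts <- as_point_matrix(points[!points$seen, c("x", "y")])
  } else {
    pts <- as_point_matrix(points)
  }
  if (nrow(pts) == 0) {
    return(structure(list(vertices = matrix(numeric(0), 0, 2),
                          points = pts, empty = TRUE),
                     class = "scotoma_hull"))
  }
  pts_u <- unique(pts)
  if (nrow(pts_u) == 1) {
    v <- pts_u
  } else {
    idx <- grDevices::chull(pts_u[, 1], pts_u[, 2])
    v <- pts_u[idx, , drop = FALSE]
    if (nrow(v) >= 3 && abs(signed_area(v)) < 1e-12) {
      # collinear: keep the two extreme endpoints
      dir <- v[which.max(rowSums((v - v[rep(1, nrow(v)), ])^2)), ] - v[1, ]
      t <- as.vector((pts_u - pts_u[rep(1, nrow(pts_u)), ]) %*% dir)
      v <- pts_u[c(which.min(t), which.max(t)), , drop = FALSE]
    }
  }
  v <- ensure_ccw(v)
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(vertices = v, points = pts, empty = FALSE),
            class = "scotoma_hull")
}

#' Hull area
#'
#' @param hull A [scotoma_hull()].
#' @return Area in deg^2 (0 for empty or degenerate hulls).
#' @export
hull_area <- function(hull) {
  stopifnot(inherits(hull, "scotoma_hull"))
  if (hull$empty) return(0)
  abs(signed_area(hull$vertices))
}

#' @export
print.scotoma_hull <- function(x, ...) {
  if (x$empty) {
    cat("scotoma_hull: empty (no unseen points)\n")
  } else {
    cat(sprintf("scotoma_hull: %d vertices, %d unseen points, area %.2f deg^2\n",
                nrow(x$vertices), nrow(x$points), hull_area(x)))
  }
  invisible(x)
}

#' Homonymous agreement between eyes
#'
#' Lists tested locations whose seen/unseen outcome disagrees between the
#' two eyes — a quick check that a field defect is homonymous. Monocular
#' fields are kept separate; no merging is performed.
#'
#' @param points Data frame with columns `x`, `y`, `eye` (`"OD"`/`"OS"`) and
#'   `seen`, containing both monocular tests.
#' @return Data frame of discordant locations with per-eye outcomes.
#' @export
homonymous_agreement <- function(points) {
  stopifnot(all(c("x", "y", "eye", "seen") %in% names(points)))
  od <- points[points$eye == "OD", ]
  os <- points[points$eye == "OS", ]
  key_od <- paste(round(od$x, 6), round(od$y, 6))
  key_os <- paste(round(os$x, 6), round(os$y, 6))
  common <- intersect(key_od, key_os)
  i_od <- match(common, key_od)
  i_os <- match(common, key_os)
  disc <- which(od$seen[i_od] != os$seen[i_os])
  data.frame(x = od$x[i_od][disc], y = od$y[i_od][disc],
             seen_od = od$seen[i_od][disc], seen_os = os$seen[i_os][disc])
}
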