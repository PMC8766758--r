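#' Diffusion acquisition scheme
#'
#' b-values and unit gradient directions, one per acquired volume. A valid
#' scheme for tensor fitting needs at least six non-collinear diffusion
#' directions plus at least one b = 0 volume.
#'
#' @param bvals Numeric b-values in s/mm^2, one per volume.
#' @param bvecs Gradient directions: matrix with one row per volume (or the
#'   FSL 3-row layout, transposed automatically). Directions for b > 0
#'   volumes must be unit norm (tolerance 1e-6).
#' @return An object of class `diffusion_scheme`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals)) {
    stop("bvecs must supply one 3-vector per b-value")
  }
  dwi <- bvals > 0
  if (sum(dwi) < 6) stop("need at least 6 diffusion-weighted directions")
  if (sum(!dwi) < 1) stop("need at least one b = 0 volume")
  norms <- sqrt(rowSums(bvecs[dwi, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("gradient directions must be unit norm (tolerance 1e-6)")
  }
  dimnames(bvecs) <- NULL
  structure(list(bvals = as.numeric(unname(bvals)), bvecs = bvecs),
            class = "diffusion_scheme")
}

#' Evenly spread gradient scheme
#'
#' Generates `n_dir` approximately uniform unit directions on the sphere
#' (Fibonacci spiral) at a single b-value, preceded by one b = 0 volume —
#' the layout of a standard 60-direction clinical acquisition.
#'
#' @param n_dir Number of diffusion-weighted directions.
#' @param bval b-value in s/mm^2.
#' @return A [diffusion_scheme()].
#' @export
make_gradient_scheme <- function(n_dir = 60, bval = 1000) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dir
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  diffusion_scheme(c(0, rep(bval, n_dir)), rbind(c(0, 0, 0), g))
}

# design matrix for the log-linear tensor fit:
# ln S = ln S0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                   + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3], 1)
}

#' Fit a single diffusion tensor to one voxel
#'
#' Log-linear least squares on `ln S = ln S0 - b g' D g` followed by
#' eigendecomposition of the fitted tensor. Non-positive signals are clamped
#' to a small floor (with a warning) before taking logs; negative
#' eigenvalues are clamped to zero and flagged.
#'
#' @param signals Numeric signal per volume.
#' @param scheme A [diffusion_scheme()].
#' @param weighted Weight the log-linear fit by squared signal (approximates
#'   uniform noise on the raw signal); default `FALSE` (unweighted).
#' @param floor Signal floor for the log transform.
#' @return An object of class `diffusion_tensor_fit`: list with `tensor`
#'   (3x3 symmetric, mm^2/s), `eigenvalues` (descending), `fa`, `md`, `s0`,
#'   `clamped`.
#' @examples
#' sch <- make_gradient_scheme()
#' D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
#' s <- make_dwi_phantom(list(D), sch, s0 = 100)
#' fit_tensor(s[1, ], sch)$fa
#' @export
fit_tensor <- function(signals, scheme, weighted = FALSE, floor = 1e-6) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  s <- as.numeric(signals)
  if (length(s) != length(scheme$bvals)) {
    stop("signals must supply one value per scheme volume")
  }
  if (any(s <= 0)) {
    warning("non-positive signals clamped to floor before log transform")
    s <- pmax(s, floor)
  }
  X <- tensor_design(scheme)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient diffusion design (collinear directions)")
  }
  w <- if (weighted) s^2 else rep(1, length(s))
  fit <- stats::lm.wfit(X, log(s), w)
  beta <- unname(fit$coefficients)
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  ev <- eigen(D, symmetric = TRUE)$values  # descending
  clamped <- any(ev < 0)
  ev <- pmax(ev, 0)
  structure(list(tensor = D, eigenvalues = ev,
                 fa = fa(ev), md = md(ev),
                 s0 = exp(beta[7]), clamped = clamped),
            class = "diffusion_tensor_fit")
}

#' Fit tensors to a matrix of voxels
#'
#' @param signals Matrix with one voxel per row, one volume per column.
#' @inheritParams fit_tensor
#' @return Data frame with per-voxel `l1`, `l2`, `l3`, `fa`, `md`, `s0`,
#'   `clamped`.
#' @export
fit_tensor_map <- function(signals, scheme, weighted = FALSE, floor = 1e-6) {
  signals <- as.matrix(signals)
  fits <- apply(signals, 1, fit_tensor, scheme = scheme,
                weighted = weighted, floor = floor)
  data.frame(l1 = vapply(fits, function(f) f$eigenvalues[1], numeric(1)),
             l2 = vapply(fits, function(f) f$eigenvalues[2], numeric(1)),
             l3 = vapply(fits, function(f) f$eigenvalues[3], numeric(1)),
             fa = vapply(fits, function(f) f$fa, numeric(1)),
             md = vapply(fits, function(f) f$md, numeric(1)),
             s0 = vapply(fits, function(f) f$s0, numeric(1)),
             clamped = vapply(fits, function(f) f$clamped, logical(1)))
}

#' Fractional anisotropy and mean diffusivity
#'
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`;
#' `MD = mean(l)`. FA of an all-zero tensor is defined as 0.
#'
#' @param eigenvalues Non-negative tensor eigenvalues (length 3).
#' @return Scalar FA in [0, 1] / MD in the eigenvalue units.
#' @examples
#' fa(c(1, 1, 1))  # 0
#' fa(c(1, 0, 0))  # 1
#' @export
fa <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  stopifnot(length(l) == 3)
  if (any(l < 0)) stop("eigenvalues must be non-negative")
  ss <- sum(l^2)
  if (ss == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(ss)
}

#' @rdname fa
#' @export
md <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  stopifnot(length(l) == 3)
  if (any(l < 0)) stop("eigenvalues must be non-negative")
  mean(l)
}

#' Tract-level volume and mean FA
#'
#' Thresholds a tract probability map (strictly greater than `threshold`, so
#' the floor value itself is excluded) and reports the volume of the
#' suprathreshold voxel set and its mean FA.
#'
#' @param fa_map 3D array of FA values.
#' @param tract_prob 3D array of tract probabilities on the same grid.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param threshold Probability threshold (default 0.001).
#' @param tract,hemisphere Optional labels carried into the result.
#' @return An object of class `tract_stats`: list with `tract`,
#'   `hemisphere`, `n_voxels`, `volume_mm3`, `mean_fa` (`NA` when the
#'   suprathreshold set is empty), `threshold`.
#' @export
tract_stats <- function(fa_map, tract_prob, voxel_size_mm = 2,
                        threshold = 0.001, tract = NA_character_,
                        hemisphere = NA_character_) {
  if (!identical(dim(fa_map), dim(tract_prob))) {
    stop("fa_map and tract_prob must share a grid")
  }
  sel <- tract_prob > threshold
  n <- sum(sel)
  vox_mm3 <- prod(rep_len(voxel_size_mm, 3))
  structure(list(tract = tract, hemisphere = hemisphere,
                 n_voxels = as.integer(n),
                 volume_mm3 = n * vox_mm3,
                 mean_fa = if (n > 0) mean(fa_map[sel]) else NA_real_,
                 threshold = threshold),
            class = "tract_stats")
}

#' Hemispheric percentage change in FA
#'
#' `100 * (lesioned - healthy) / healthy`; a reduction in the lesioned
#' hemisphere is negative.
#'
#' @param lesioned_mean_fa,healthy_mean_fa Mean FA over the tract in each
#'   hemisphere; `healthy_mean_fa` must be positive.
#' @return Percentage change.
#' @examples
#' fa_change(0.30, 0.50)  # -40
#' @export
fa_change <- function(lesioned_mean_fa, healthy_mean_fa) {
  if (healthy_mean_fa <= 0) stop("healthy_mean_fa must be positive")
  100 * (lesioned_mean_fa - healthy_mean_fa) / healthy_mean_fa
}

#' Read / write FSL-dialect gradient files
#'
#' `bvals` is a single whitespace-separated row of b-values; `bvecs` holds
#' three whitespace-separated rows (x, y, z components).
#'
#' @param bvals_path,bvecs_path File paths.
#' @return `read_bvals_bvecs` returns a [diffusion_scheme()];
#'   `write_bvals_bvecs` returns the paths invisibly.
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  rows <- readLines(bvecs_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3) stop("bvecs must contain 3 rows")
  bvecs <- t(vapply(rows, function(r) scan(text = r, quiet = TRUE),
                    numeric(length(bvals))))
  diffusion_scheme(bvals, t(bvecs))
}

#' @rdname read_bvals_bvecs
#' @param scheme A [diffusion_scheme()] to write.
#' @export
write_bvals_bvecs <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  }), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}
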