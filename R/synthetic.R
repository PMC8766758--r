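# Synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth, so all stages are testable without
# participant data. All generators are pure functions of (config, seed);
# the RNG state of the caller is restored on exit.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  code
}

#' Simulation configuration
#'
#' Conditions for the synthetic cortical sheet. Defaults mirror the
#' acquisition the pipeline targets: TR 1.5 s, 24 s stimulus period, five
#' cycles per run, wedge + ring + bar runs, measurement noise with standard
#' deviation 0.2 x response amplitude, and a pRF size growing linearly with
#' eccentricity (`sigma = 0.1 + 0.25 * eccentricity`).
#'
#' @param field_radius Mapped field radius in degrees.
#' @param n_voxels Visually responsive voxels per hemisphere.
#' @param n_control Noise-only control voxels (non-visual cortex), used to
#'   derive the reliability threshold.
#' @param noise_sd Noise standard deviation as a fraction of the response
#'   amplitude.
#' @param noise_ar1_rho AR(1) coefficient of the noise (0 = white).
#' @param ipsi_strip_deg Width of the ipsilateral strip of visual field each
#'   hemisphere also represents, in degrees.
#' @param sigma_intercept,sigma_slope Linear pRF size-eccentricity relation
#'   (degrees, degrees/degree).
#' @param amplitude Response amplitude (signal units).
#' @param tr_s,period_s,n_cycles Stimulus timing.
#' @param aperture_kinds Which runs to simulate.
#' @param grid_n Aperture grid resolution per axis.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(field_radius = 10, n_voxels = 200,
                              n_control = 50, noise_sd = 0.2,
                              noise_ar1_rho = 0, ipsi_strip_deg = 1,
                              sigma_intercept = 0.1, sigma_slope = 0.25,
                              amplitude = 1, tr_s = 1.5, period_s = 24,
                              n_cycles = 5,
                              aperture_kinds = c("wedge", "ring", "bar"),
                              grid_n = 101) {
  fpc <- period_s / tr_s
  if (abs(fpc - round(fpc)) > 1e-9) {
    stop("period_s must be an integer multiple of tr_s")
  }
  structure(as.list(environment()), class = "simulation_config")
}

default_apertures <- function(config) {
  lapply(config$aperture_kinds, function(kind) {
    make_aperture(kind, field_radius = config$field_radius,
                  period_s = config$period_s, n_cycles = config$n_cycles,
                  tr_s = config$tr_s, grid_n = config$grid_n)
  })
}

# seeded noise matrix (white or AR(1)), one voxel per column
noise_matrix <- function(n_time, n_vox, sd, rho = 0) {
  e <- matrix(stats::rnorm(n_time * n_vox, sd = sd), n_time, n_vox)
  if (rho != 0) {
    e <- apply(e, 2, function(x) {
      as.numeric(stats::filter(x, rho, method = "recursive"))
    }) * sqrt(1 - rho^2)
  }
  e
}

# is the disc (center, radius) entirely inside the polygon?
disc_inside_polygon <- function(centers, radii, poly) {
  inside <- points_in_polygon(centers, poly)
  inside & dist_points_boundary(centers, poly) >= radii
}

#' Generate a synthetic cortical sheet with ground-truth pRFs
#'
#' Draws per-voxel ground-truth pRFs that tile each hemisphere's
#' contralateral hemifield (plus a small ipsilateral strip), with pRF size
#' increasing linearly with eccentricity, and simulates BOLD-like responses
#' to the configured aperture runs plus seeded Gaussian noise. Voxels of the
#' lesioned hemisphere whose true pRF disc lies entirely inside the scotoma
#' polygon are flagged lesioned and their series replaced by pure noise.
#' Noise-only control voxels (the non-visual control region) are appended.
#'
#' The lesioned hemisphere represents the left visual hemifield (centers at
#' x <= ipsilateral strip), the healthy hemisphere the right.
#'
#' @param config A [simulation_config()].
#' @param scotoma Optional polygon (matrix of vertices, degrees) describing
#'   the field region silenced by the lesion; may extend beyond the mapped
#'   field (a cortical lesion silencing the full contralateral map) but must
#'   overlap it. `NULL` = no lesion.
#' @param seed Integer seed; the same seed reproduces the sheet bit for bit.
#' @param apertures Optional pre-built aperture list (must match the
#'   config's timing); built from the config when `NULL`.
#' @param hrf An [hrf_model()].
#' @param symmetric Make the brain exactly mirror-symmetric: the healthy
#'   hemisphere's ground-truth pRFs are the lesioned hemisphere's reflected
#'   across the vertical meridian (noise stays independent). Used to
#'   validate the mirror-flip control under the null.
#' @return An object of class `ground_truth_sheet`: list with `truth` (data
#'   frame: voxel, i, j, k, hemisphere, roi, x0, y0, sigma, amplitude,
#'   lesion), `series` (frames x voxels matrix, controls last), `apertures`,
#'   `hrf`, `config`, `seed`.
#' @export
make_sheet <- function(config = simulation_config(), scotoma = NULL,
                       seed = 1, apertures = NULL, hrf = hrf_model(),
                       symmetric = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  R <- config$field_radius
  if (!is.null(scotoma)) {
    scotoma <- as_point_matrix(scotoma)
    probe <- as.matrix(expand.grid(x = seq(-R, R, length.out = 21),
                                   y = seq(-R, R, length.out = 21)))
    probe <- probe[sqrt(probe[, 1]^2 + probe[, 2]^2) <= R, , drop = FALSE]
    if (!any(points_in_polygon(probe, scotoma))) {
      stop("scotoma polygon lies outside the mapped field radius")
    }
  }
  if (is.null(apertures)) apertures <- default_apertures(config)

  with_seed(seed, {
    sample_hemifield <- function(n, side) {
      # quasi-uniform centers over the half-disc plus the ipsilateral strip
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < n) {
        m <- 2 * (n - nrow(out)) + 20
        x <- stats::runif(m, -R, R)
        y <- stats::runif(m, -R, R)
        ok <- sqrt(x^2 + y^2) <= R &
          (if (side == "left") x <= config$ipsi_strip_deg
           else x >= -config$ipsi_strip_deg)
        out <- rbind(out, cbind(x[ok], y[ok]))
      }
      out[seq_len(n), , drop = FALSE]
    }
    hemi_truth <- function(h, ctr) {
      ecc <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
      data.frame(hemisphere = h,
                 roi = ifelse(ctr[, 2] >= 0, "V1v", "V1d"),
                 x0 = ctr[, 1], y0 = ctr[, 2],
                 sigma = config$sigma_intercept + config$sigma_slope * ecc,
                 amplitude = config$amplitude,
                 lesion = FALSE)
    }
    ctr_les <- sample_hemifield(config$n_voxels, "left")
    ctr_hea <- if (symmetric) {
      cbind(-ctr_les[, 1], ctr_les[, 2])
    } else {
      sample_hemifield(config$n_voxels, "right")
    }
    truth <- rbind(hemi_truth("lesioned", ctr_les),
                   hemi_truth("healthy", ctr_hea))
    if (!is.null(scotoma)) {
      les <- truth$hemisphere == "lesioned"
      truth$lesion[les] <- disc_inside_polygon(
        cbind(truth$x0[les], truth$y0[les]), truth$sigma[les], scotoma)
    }
    n_vis <- nrow(truth)
    ctrl <- data.frame(hemisphere = "control", roi = "PFC",
                       x0 = NA_real_, y0 = NA_real_, sigma = NA_real_,
                       amplitude = 0,
                       lesion = FALSE)[rep(1, config$n_control), ]
    truth <- rbind(truth, ctrl)
    truth$voxel <- seq_len(nrow(truth))
    # native-grid voxel indices on a nominal 3 mm acquisition lattice
    nx <- 10L
    truth$i <- (truth$voxel - 1L) %% nx
    truth$j <- ((truth$voxel - 1L) %/% nx) %% nx
    truth$k <- (truth$voxel - 1L) %/% (nx * nx)
    truth <- truth[, c("voxel", "i", "j", "k", "hemisphere", "roi",
                       "x0", "y0", "sigma", "amplitude", "lesion")]
    rownames(truth) <- NULL

    n_time <- sum(vapply(apertures, function(a) dim(a$frames)[3],
                         integer(1)))
    vis <- truth[seq_len(n_vis), ]
    signal <- build_predictors(apertures, hrf, vis$x0, vis$y0, vis$sigma,
                               filter = FALSE)
    signal <- sweep(signal, 2, vis$amplitude, `*`)
    signal[, vis$lesion] <- 0
    signal <- cbind(signal, matrix(0, n_time, config$n_control))
    series <- signal + noise_matrix(n_time, nrow(truth),
                                    config$noise_sd * config$amplitude,
                                    config$noise_ar1_rho)
    structure(list(truth = truth, series = series, apertures = apertures,
                   hrf = hrf, config = config, seed = seed),
              class = "ground_truth_sheet")
  })
}

#' Simulate a full study scenario
#'
#' Bundles the generators into the three study conditions: `"hemianopia"`
#' (complete loss of the left hemifield — the entire contralateral map of
#' the lesioned hemisphere is silenced), `"quadrantanopia"` (lower-left
#' quadrant) and `"control"` (no lesion). Returns the cortical sheet, a
#' synthetic perimetry responder, and the scotoma hull derived from its
#' unseen points.
#'
#' @param scenario One of `"hemianopia"`, `"quadrantanopia"`, `"control"`.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param perimetry_extent,perimetry_step Synthetic perimetry grid geometry
#'   in degrees.
#' @return List with `sheet`, `perimetry`, `hull`, `scotoma_polygon` (the
#'   perimetry-facing blind region; `NULL` for control), `scenario`.
#' @export
simulate_scenario <- function(scenario = c("hemianopia", "quadrantanopia",
                                           "control"),
                              config = simulation_config(), seed = 1,
                              perimetry_extent = 25, perimetry_step = 2) {
  scenario <- match.arg(scenario)
  e <- perimetry_extent + 2
  big <- 3 * config$field_radius + perimetry_extent
  field_poly <- switch(scenario,
    hemianopia = rbind(c(0, -e), c(0, e), c(-e, e), c(-e, -e)),
    quadrantanopia = rbind(c(0, 0), c(0, -e), c(-e, -e), c(-e, 0)),
    control = NULL)
  lesion_poly <- switch(scenario,
    # cortical-lesion proxy: generous margins so every pRF disc of the
    # affected map lies inside the silenced region
    hemianopia = rbind(c(big, -big), c(big, big), c(-big, big),
                       c(-big, -big)),
    quadrantanopia = rbind(c(0, 0), c(0, -big), c(-big, -big), c(-big, 0)),
    control = NULL)
  sheet <- make_sheet(config, scotoma = lesion_poly, seed = seed)
  perimetry <- make_perimetry_responder(field_poly, grid_step = perimetry_step,
                                        extent = perimetry_extent,
                                        seed = seed + 1)
  hull <- scotoma_hull(perimetry)
  list(sheet = sheet, perimetry = perimetry, hull = hull,
       scotoma_polygon = field_poly, scenario = scenario)
}

#' Synthetic perimetry responder
#'
#' Regular test grid over the field; points strictly inside the scotoma
#' polygon are unseen, all others respond at the age-normal threshold
#' (optionally with seeded jitter). Points on the polygon boundary — e.g.
#' along the vertical meridian — are treated as seen.
#'
#' @param scotoma Polygon (matrix of vertices, degrees) or `NULL` for an
#'   intact field.
#' @param grid_step Grid spacing in degrees.
#' @param extent Maximum eccentricity tested, degrees.
#' @param normals Normative field (see [normal_db()]).
#' @param eye `"OD"` or `"OS"`.
#' @param jitter_sd SD of threshold jitter in dB (0 = none).
#' @param seed Integer seed (used only when jitter is requested).
#' @return Data frame with columns `x`, `y`, `eye`, `threshold_db` (`NA`
#'   when unseen), `seen`.
#' @export
make_perimetry_responder <- function(scotoma = NULL, grid_step = 2,
                                     extent = 25,
                                     normals = normative_field(),
                                     eye = "OD", jitter_sd = 0,
                                     seed = NULL) {
  stopifnot(grid_step > 0)
  ax <- seq(-extent, extent, by = grid_step)
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  g <- g[sqrt(g$x^2 + g$y^2) <= extent, , drop = FALSE]
  seen <- rep(TRUE, nrow(g))
  if (!is.null(scotoma)) {
    poly <- as_point_matrix(scotoma)
    p <- as.matrix(g)
    strict <- points_in_polygon(p, poly) &
      dist_points_boundary(p, poly) > 1e-9
    seen <- !strict
  }
  thr <- normal_db(normals, g$x, g$y)
  if (jitter_sd > 0) {
    thr <- with_seed(seed, thr + stats::rnorm(length(thr), sd = jitter_sd))
  }
  out <- data.frame(x = g$x, y = g$y, eye = eye,
                    threshold_db = ifelse(seen, thr, NA_real_),
                    seen = seen)
  rownames(out) <- NULL
  out
}

#' Seeded bivariate-normal fixation cloud
#'
#' @param sigma_h,sigma_v Standard deviations in degrees (positive).
#' @param rho Correlation, strictly inside (-1, 1).
#' @param n Number of samples (>= 3).
#' @param seed Integer seed.
#' @return `n x 2` matrix of positions (columns `x`, `y`).
#' @export
make_fixation_cloud <- function(sigma_h, sigma_v, rho, n, seed = 1) {
  if (sigma_h <= 0 || sigma_v <= 0 || abs(rho) >= 1) {
    stop("invalid covariance: need positive sigmas and |rho| < 1")
  }
  if (n < 3) stop("need n >= 3 samples")
  S <- matrix(c(sigma_h^2, rho * sigma_h * sigma_v,
                rho * sigma_h * sigma_v, sigma_v^2), 2, 2)
  with_seed(seed, {
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(S)
    colnames(z) <- c("x", "y")
    z
  })
}

#' Synthetic diffusion-weighted signals
#'
#' Forward single-tensor model `S = S0 exp(-b g' D g)` per voxel, with
#' optional seeded noise (additive Gaussian by default; Rician — Gaussian on
#' the complex components followed by magnitude — on request).
#'
#' @param tensors List of symmetric positive-definite 3x3 tensors (mm^2/s),
#'   one per voxel.
#' @param scheme A [diffusion_scheme()].
#' @param s0 Non-diffusion-weighted signal.
#' @param noise_sd Noise SD in signal units (0 = noiseless).
#' @param seed Integer seed.
#' @param rician Use Rician magnitude noise.
#' @return Matrix of signals, one voxel per row, one volume per column.
#' @export
make_dwi_phantom <- function(tensors, scheme, s0 = 100, noise_sd = 0,
                             seed = 1, rician = FALSE) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  if (!is.list(tensors)) tensors <- list(tensors)
  for (D in tensors) {
    if (!isTRUE(all.equal(D, t(D))) ||
        any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("tensors must be symmetric positive definite")
    }
  }
  g <- scheme$bvecs
  b <- scheme$bvals
  S <- t(vapply(tensors, function(D) {
    s0 * exp(-b * rowSums((g %*% D) * g))
  }, numeric(length(b))))
  if (noise_sd > 0) {
    S <- with_seed(seed, {
      if (rician) {
        re <- S + matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S))
        im <- matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S))
        sqrt(re^2 + im^2)
      } else {
        S + matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S))
      }
    })
  }
  S
}

#' Shrink a tensor toward isotropy to hit a target FA ratio
#'
#' Interpolates the eigenvalues toward their mean until the FA equals
#' `fa_ratio` times the original FA (mean diffusivity is preserved). Used to
#' engineer hemispheric FA asymmetries with known ground truth.
#'
#' @param D Symmetric positive-definite tensor.
#' @param fa_ratio Target FA as a fraction of the original FA, in (0, 1].
#' @return The modified tensor.
#' @export
make_fa_scaled_tensor <- function(D, fa_ratio) {
  stopifnot(fa_ratio > 0, fa_ratio <= 1)
  e <- eigen(D, symmetric = TRUE)
  target <- fa_ratio * fa(pmax(e$values, 0))
  f <- function(t) {
    fa(pmax((1 - t) * e$values + t * mean(e$values), 0)) - target
  }
  t_star <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  lam <- (1 - t_star) * e$values + t_star * mean(e$values)
  e$vectors %*% diag(lam) %*% t(e$vectors)
}

#' Toy 25-ROI atlas with an engineered lesion
#'
#' Builds a label volume with 25 disjoint box-shaped ROIs per hemisphere
#' (200 voxels each on the default grid) and a binary lesion mask covering a
#' specified exact fraction of chosen ROIs, so atlas-overlap percentages
#' have a known ground truth. Custom box layouts are checked for
#' disjointness.
#'
#' @param lesion_fractions Named numeric vector, ROI name -> fraction of the
#'   ROI to cover (0-1). Fractions must be exactly representable in voxels.
#' @param hemisphere Hemisphere carrying the lesion (`"left"`/`"right"`).
#' @param boxes Optional custom layout: data frame with columns `roi`,
#'   `hemisphere`, `x0`, `x1`, `y0`, `y1`, `z0`, `z1` (inclusive voxel index
#'   ranges). Overlapping boxes raise an error.
#' @param dim_xyz Grid dimensions for the default layout.
#' @return List with `atlas` (an [atlas_volume()]), `lesion` (binary array)
#'   and `expected` (data frame roi, hemisphere, loss_pct).
#' @export
make_toy_atlas_and_lesion <- function(lesion_fractions = c(V1d = 0.3),
                                      hemisphere = "left",
                                      boxes = NULL,
                                      dim_xyz = c(14L, 48L, 32L)) {
  rois <- names(wang_territories())
  if (is.null(boxes)) {
    lay <- expand.grid(iy = 0:4, iz = 0:4)[seq_along(rois), ]
    boxes <- do.call(rbind, lapply(c("left", "right"), function(h) {
      x0 <- if (h == "left") 2L else 9L
      data.frame(roi = rois, hemisphere = h,
                 x0 = x0, x1 = x0 + 4L,
                 y0 = 2L + lay$iy * 9L, y1 = 2L + lay$iy * 9L + 7L,
                 z0 = 2L + lay$iz * 6L, z1 = 2L + lay$iz * 6L + 4L)
    }))
  }
  if (any(boxes$x1 > dim_xyz[1] | boxes$y1 > dim_xyz[2] |
            boxes$z1 > dim_xyz[3] | boxes$x0 < 1)) {
    stop("ROI boxes exceed the grid")
  }
  labels <- array(0L, dim = dim_xyz)
  for (r in seq_len(nrow(boxes))) {
    b <- boxes[r, ]
    block <- labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1]
    if (any(block != 0)) {
      stop(sprintf("overlapping ROI boxes at %s (%s)", b$roi, b$hemisphere))
    }
    labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <- r
  }
  label_table <- data.frame(label = seq_len(nrow(boxes)),
                            roi = boxes$roi, hemisphere = boxes$hemisphere)
  lesion <- array(0L, dim = dim_xyz)
  expected <- data.frame(roi = character(0), hemisphere = character(0),
                         loss_pct = numeric(0))
  for (roi in names(lesion_fractions)) {
    frac <- lesion_fractions[[roi]]
    lab <- label_table$label[label_table$roi == roi &
                               label_table$hemisphere == hemisphere]
    if (length(lab) != 1) stop("unknown ROI name: ", roi)
    vox <- which(labels == lab)
    k <- frac * length(vox)
    if (abs(k - round(k)) > 1e-9) {
      stop(sprintf("fraction %g of %d voxels is not an integer voxel count",
                   frac, length(vox)))
    }
    lesion[vox[seq_len(round(k))]] <- 1L
    expected <- rbind(expected,
                      data.frame(roi = roi, hemisphere = hemisphere,
                                 loss_pct = 100 * frac))
  }
  list(atlas = atlas_volume(labels, voxel_size_mm = 1,
                            label_table = label_table),
       lesion = lesion, expected = expected)
}
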