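#' Canonical hemodynamic response model
#'
#' A double-gamma impulse response: a positive gamma lobe peaking at
#' `peak_s` minus a later gamma lobe (the post-stimulus undershoot) peaking at
#' `undershoot_s`, scaled down by `ratio`. Both lobes use unit-rate gamma
#' densities, so the mode of each lobe equals its stated delay.
#'
#' @param peak_s Time-to-peak of the positive lobe in seconds.
#' @param undershoot_s Time-to-trough of the undershoot in seconds; must
#'   exceed `peak_s`.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel support in seconds.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak_s = 5, undershoot_s = 15, ratio = 6, length_s = 30) {
  if (any(c(peak_s, undershoot_s, ratio, length_s) <= 0)) {
    stop("all HRF parameters must be positive")
  }
  if (undershoot_s <= peak_s) stop("undershoot_s must exceed peak_s")
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 ratio = ratio, length_s = length_s),
            class = "hrf_model")
}

#' Sample an HRF kernel at the TR
#'
#' @param model An [hrf_model()].
#' @param tr_s Sampling interval (volume TR) in seconds.
#' @return Numeric kernel sampled at `0, tr_s, 2 tr_s, ...` up to the model
#'   length, peak-normalized to 1. The value at t = 0 is exactly 0.
#' @export
hrf_kernel <- function(model = hrf_model(), tr_s = 1.5) {
  stopifnot(inherits(model, "hrf_model"))
  if (tr_s <= 0) stop("tr_s must be positive")
  t <- seq(0, model$length_s, by = tr_s)
  h <- stats::dgamma(t, shape = model$peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = model$undershoot_s + 1, rate = 1) / model$ratio
  h / max(h)
}

#' Temporal high-pass filter
#'
#' Removes slow signal drift by zeroing all Fourier components below the
#' cutoff frequency (including the mean), the standard pre-processing step
#' before pRF fitting. Accepts a vector or a matrix of column time series.
#'
#' @param series Numeric vector, or matrix with one time series per column.
#' @param tr_s Sampling interval in seconds.
#' @param cutoff_hz Cutoff frequency in Hz; components below it are removed.
#' @return Filtered series of the same shape, zero-mean.
#' @export
highpass_filter <- function(series, tr_s, cutoff_hz = 0.01) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 8) stop("series too short to filter (need >= 8 samples)")
  if (tr_s <= 0 || cutoff_hz <= 0) stop("tr_s and cutoff_hz must be positive")
  freq <- (seq_len(n) - 1) / (n * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)  # fold to two-sided spectrum
  keep <- freq >= cutoff_hz
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  if (is.vector(series)) drop(out) else out
}

# causal linear convolution with an HRF kernel, truncated to input length;
# operates columnwise on a matrix
convolve_hrf <- function(x, kernel) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(kernel)) {
    if (kernel[k] == 0) next
    idx <- k:n
    out[idx, ] <- out[idx, ] + kernel[k] * x[idx - k + 1, , drop = FALSE]
  }
  out
}

# unit-mass 2D Gaussian profiles on an aperture grid; one column per pRF
gaussian_profiles <- function(aperture, x0, y0, sigma, normalize = TRUE) {
  gx <- aperture$grid_x
  gy <- aperture$grid_y
  nx <- length(gx)
  ny <- length(gy)
  m <- length(x0)
  G <- matrix(0, nx * ny, m)
  X <- matrix(gx, nx, ny)
  Y <- matrix(gy, nx, ny, byrow = TRUE)
  for (j in seq_len(m)) {
    g <- exp(-((X - x0[j])^2 + (Y - y0[j])^2) / (2 * sigma[j]^2))
    s <- sum(g)
    if (normalize && s > 0) g <- g / s
    G[, j] <- g
  }
  G
}

# precomputed per-run context for fast repeated prediction during the
# refinement stage: aperture design matrix, pixel coordinates, HRF kernel
# and high-pass mask are built once per fit
prediction_context <- function(apertures, hrf, cutoff_hz = 0.01) {
  runs <- lapply(apertures, function(ap) {
    nx <- length(ap$grid_x)
    ny <- length(ap$grid_y)
    # HRF convolution and high-pass are linear in time, so they are applied
    # to the aperture design matrix once; prediction is then one mat-vec
    B <- convolve_hrf(aperture_matrix(ap), hrf_kernel(hrf, ap$tr_s))
    B <- highpass_filter(B, ap$tr_s, cutoff_hz)
    list(B = B,
         px = rep(ap$grid_x, ny),
         py = rep(ap$grid_y, each = nx),
         n_t = dim(ap$frames)[3])
  })
  # runs on identical grids share one stacked design matrix (common case)
  same_grid <- length(runs) > 1 &&
    all(vapply(runs[-1], function(r) {
      identical(r$px, runs[[1]]$px) && identical(r$py, runs[[1]]$py)
    }, logical(1)))
  if (same_grid) {
    runs <- list(list(B = do.call(rbind, lapply(runs, `[[`, "B")),
                      px = runs[[1]]$px, py = runs[[1]]$py,
                      n_t = sum(vapply(runs, `[[`, integer(1), "n_t"))))
  }
  runs
}

# filtered prediction for one pRF using a prediction_context; the Gaussian
# is evaluated only on its numerically relevant support
predict_from_context <- function(ctx, x0, y0, sigma) {
  unlist(lapply(ctx, function(run) {
    d2 <- (run$px - x0)^2 + (run$py - y0)^2
    lim <- 2 * sigma^2 * 40  # exp(-40) ~ 4e-18: below double precision
    small <- d2 < lim
    n_on <- sum(small)
    if (n_on == 0) return(numeric(run$n_t))
    if (n_on < length(d2) / 4) {
      idx <- which(small)  # narrow pRF: restrict the mat-vec to its support
      g <- exp(-d2[idx] / (2 * sigma^2))
      drop(run$B[, idx, drop = FALSE] %*% g) / sum(g)
    } else {
      g <- exp(-d2 / (2 * sigma^2))
      drop(run$B %*% g) / sum(g)
    }
  }), use.names = FALSE)
}

# stimulus-driven predictions for a set of candidate pRFs across runs:
# overlap per frame -> causal HRF convolution per run -> high-pass per run,
# runs concatenated row-wise
build_predictors <- function(apertures, hrf, x0, y0, sigma,
                             cutoff_hz = 0.01, filter = TRUE) {
  if (inherits(apertures, "aperture_movie")) apertures <- list(apertures)
  blocks <- lapply(apertures, function(ap) {
    A <- aperture_matrix(ap)
    kernel <- hrf_kernel(hrf, ap$tr_s)
    M <- A %*% gaussian_profiles(ap, x0, y0, sigma)
    M <- convolve_hrf(M, kernel)
    if (filter) M <- highpass_filter(M, ap$tr_s, cutoff_hz)
    M
  })
  do.call(rbind, blocks)
}

#' Predict a BOLD time series from pRF parameters
#'
#' The per-frame response is the overlap between the binary aperture and a
#' unit-mass 2D Gaussian receptive field, convolved with the hemodynamic
#' kernel (causal, truncated to the series length) and scaled by the
#' amplitude.
#'
#' @param params List or named vector with `x0`, `y0`, `sigma` (degrees) and
#'   optionally `amplitude` (default 1).
#' @param aperture An [make_aperture()] movie, or a list of movies (runs are
#'   convolved separately and concatenated).
#' @param hrf An [hrf_model()]; set to `NULL` to skip convolution and return
#'   the raw overlap time course.
#' @return Numeric predicted series, one value per frame.
#' @export
predict_timeseries <- function(params, aperture, hrf = hrf_model()) {
  p <- as.list(params)
  if (is.null(p$amplitude)) p$amplitude <- 1
  if (p$sigma <= 0) stop("sigma must be positive")
  aps <- if (inherits(aperture, "aperture_movie")) list(aperture) else aperture
  step <- diff(aps[[1]]$grid_x[1:2])
  if (p$sigma < step / 2) {
    warning(sprintf("sigma (%g deg) is below half the grid step (%g deg); quadrature may be coarse",
                    p$sigma, step))
  }
  blocks <- lapply(aps, function(ap) {
    ov <- drop(aperture_matrix(ap) %*%
                 gaussian_profiles(ap, p$x0, p$y0, p$sigma))
    if (is.null(hrf)) ov else drop(convolve_hrf(ov, hrf_kernel(hrf, ap$tr_s)))
  })
  p$amplitude * unlist(blocks, use.names = FALSE)
}

#' Search grid for coarse-to-fine pRF fitting
#'
#' @param field_radius Mapped field radius in degrees; centers span
#'   `±field_radius` on an `n_xy` x `n_xy` lattice and may move out to
#'   `±center_factor * field_radius` during refinement.
#' @param n_xy Lattice points per axis for the coarse stage.
#' @param sigmas Candidate pRF sizes (degrees) for the coarse stage.
#' @param center_factor Refinement bound on centers, in units of
#'   `field_radius`.
#' @param sigma_bounds Refinement bounds on sigma in degrees.
#' @param refine_starts Number of best grid nodes used as starting points
#'   for the nonlinear stage; restarting from a few distinct nodes guards
#'   against local minima of the residual surface.
#' @return An object of class `prf_search`.
#' @export
prf_search_grid <- function(field_radius = 10, n_xy = 17,
                            sigmas = c(0.5, 1, 2, 4),
                            center_factor = 1.5,
                            sigma_bounds = c(0.1, field_radius),
                            refine_starts = 3) {
  ax <- seq(-field_radius, field_radius, length.out = n_xy)
  nodes <- expand.grid(x0 = ax, y0 = ax, sigma = sigmas,
                       KEEP.OUT.ATTRS = FALSE)
  structure(list(nodes = nodes, field_radius = field_radius,
                 refine_starts = max(1L, as.integer(refine_starts)),
                 lower = c(-center_factor * field_radius,
                           -center_factor * field_radius, sigma_bounds[1]),
                 upper = c(center_factor * field_radius,
                           center_factor * field_radius, sigma_bounds[2])),
            class = "prf_search")
}

#' Fit circular Gaussian pRFs to voxel time series
#'
#' Coarse-to-fine nonlinear least squares: a grid search over candidate
#' centers and sizes with the amplitude solved in closed form at each node,
#' followed (optionally) by bounded quasi-Newton refinement of
#' `(x0, y0, sigma)`. Goodness of fit is the coefficient of determination
#' `r2 = 1 - SS_res / SS_tot` on the high-pass-filtered series. Ties in the
#' grid stage are broken by the first node in row-major order; the whole fit
#' is deterministic.
#'
#' Zero-variance (constant) series are returned with `r2 = 0` and
#' `degenerate = TRUE` rather than raising an error.
#'
#' @param series Numeric matrix of observed time series, one voxel per
#'   column (rows = concatenated run frames matching `apertures`), or a
#'   vector for a single voxel.
#' @param apertures An `aperture_movie` or list of movies (one per run).
#' @param hrf An [hrf_model()].
#' @param search A [prf_search_grid()].
#' @param cutoff_hz High-pass cutoff applied to data and predictions.
#' @param refine Run the nonlinear refinement stage (default `TRUE`); when
#'   `FALSE` the grid-stage estimates are returned.
#' @param filter_series Set `FALSE` if `series` is already filtered.
#' @param voxel_id Optional data frame / matrix of voxel identifiers (e.g.
#'   columns `i`, `j`, `k`), one row per voxel, carried into the result.
#' @return A data frame of class `prf_fits` with one row per voxel:
#'   `voxel`, `x0`, `y0`, `sigma`, `amplitude`, `r2`, `degenerate`
#'   (plus any `voxel_id` columns).
#' @examples
#' ap <- make_aperture("wedge", field_radius = 8, grid_n = 41)
#' y <- predict_timeseries(list(x0 = 3, y0 = -2, sigma = 1.5), ap)
#' fit <- fit_prf(y, ap, search = prf_search_grid(8, n_xy = 9))
#' @export
fit_prf <- function(series, apertures, hrf = hrf_model(),
                    search = prf_search_grid(),
                    cutoff_hz = 0.01, refine = TRUE,
                    filter_series = TRUE, voxel_id = NULL) {
  Y <- as.matrix(series)
  if (any(!is.finite(Y))) stop("series must be finite")
  input_var <- apply(Y, 2, stats::var)
  if (inherits(apertures, "aperture_movie")) apertures <- list(apertures)
  run_len <- vapply(apertures, function(ap) dim(ap$frames)[3], integer(1))
  if (nrow(Y) != sum(run_len)) {
    stop(sprintf("series has %d rows but apertures supply %d frames",
                 nrow(Y), sum(run_len)))
  }
  if (filter_series) {
    ends <- cumsum(run_len)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    for (r in seq_along(run_len)) {
      idx <- starts[r]:ends[r]
      Y[idx, ] <- highpass_filter(Y[idx, , drop = FALSE],
                                  apertures[[r]]$tr_s, cutoff_hz)
    }
  } else {
    Y <- sweep(Y, 2, colMeans(Y))
  }

  nodes <- search$nodes
  P <- build_predictors(apertures, hrf, nodes$x0, nodes$y0, nodes$sigma,
                        cutoff_hz = cutoff_hz)
  pp <- colSums(P^2)
  ok <- pp > 0
  yy <- colSums(Y^2)
  num <- crossprod(P, Y)                       # nodes x voxels
  gain <- (num / ifelse(ok, sqrt(pp), Inf))^2  # SS explained per node
  gain[!ok, ] <- 0
  best <- apply(gain, 2, which.max)

  n_vox <- ncol(Y)
  out <- data.frame(voxel = seq_len(n_vox),
                    x0 = nodes$x0[best], y0 = nodes$y0[best],
                    sigma = nodes$sigma[best],
                    amplitude = num[cbind(best, seq_len(n_vox))] / pp[best],
                    r2 = NA_real_,
                    degenerate = input_var == 0 | yy <= 1e-20 * nrow(Y))
  rss <- yy - gain[cbind(best, seq_len(n_vox))]

  ctx <- prediction_context(apertures, hrf, cutoff_hz)
  objective <- function(theta, y) {
    p <- predict_from_context(ctx, theta[1], theta[2], theta[3])
    ss <- sum(p^2)
    if (!is.finite(ss) || ss <= 0) return(sum(y^2))
    q <- p / sqrt(ss)  # unit-norm predictor: overflow-safe projection
    sum(y^2) - sum(q * y)^2
  }

  n_starts <- if (is.null(search$refine_starts)) 1L else search$refine_starts
  for (v in seq_len(n_vox)) {
    if (out$degenerate[v]) next
    if (refine) {
      # restart from the best few grid nodes at well-separated centers
      ord <- order(gain[, v], decreasing = TRUE)
      starts <- ord[1]
      for (cand in ord[-1]) {
        if (length(starts) >= n_starts) break
        d <- sqrt((nodes$x0[cand] - nodes$x0[starts])^2 +
                    (nodes$y0[cand] - nodes$y0[starts])^2)
        if (all(d > 1e-9)) starts <- c(starts, cand)
      }
      for (s in starts) {
        start <- c(nodes$x0[s], nodes$y0[s],
                   max(nodes$sigma[s], search$lower[3]))
        opt <- stats::optim(start, objective, y = Y[, v],
                            method = "L-BFGS-B",
                            lower = search$lower, upper = search$upper,
                            control = list(factr = 1e7))
        if (opt$value < rss[v]) {
          rss[v] <- opt$value
          out$x0[v] <- opt$par[1]
          out$y0[v] <- opt$par[2]
          out$sigma[v] <- opt$par[3]
          p <- predict_from_context(ctx, opt$par[1], opt$par[2], opt$par[3])
          ss <- sum(p^2)
          out$amplitude[v] <- if (ss > 0) sum(p * Y[, v]) / ss else 0
        }
      }
    }
    out$r2[v] <- 1 - rss[v] / yy[v]
  }
  out$r2[out$degenerate] <- 0
  out$amplitude[out$degenerate] <- 0
  out$x0[out$degenerate] <- NA_real_
  out$y0[out$degenerate] <- NA_real_
  out$sigma[out$degenerate] <- NA_real_
  out$r2 <- pmin(pmax(out$r2, 0), 1)
  if (!is.null(voxel_id)) out <- cbind(out, as.data.frame(voxel_id))
  class(out) <- c("prf_fits", "data.frame")
  out
}

#' Reliability threshold from a control region
#'
#' The threshold for calling a pRF estimate reliable is referenced to a
#' non-visually-responsive control region: mean plus three sample standard
#' deviations of the control voxels' r-squared values.
#'
#' @param control_r2 Numeric r-squared values from the control ROI (>= 2).
#' @return The scalar threshold.
#' @examples
#' reliability_threshold(c(0.1, 0.2, 0.3))  # 0.2 + 3 * 0.1 = 0.5
#' @export
reliability_threshold <- function(control_r2) {
  control_r2 <- as.numeric(control_r2)
  if (length(control_r2) < 2) {
    stop("need at least 2 control r2 values to form a threshold")
  }
  mean(control_r2) + 3 * stats::sd(control_r2)
}

#' Flag reliable fits
#'
#' @param fits A `prf_fits` data frame.
#' @param threshold Reliability threshold on r-squared (see
#'   [reliability_threshold()]).
#' @return `fits` with a logical `reliable` column (`r2 >= threshold`).
#' @export
flag_reliable <- function(fits, threshold) {
  fits$reliable <- fits$r2 >= threshold
  fits
}
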