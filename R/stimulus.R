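#' Screen geometry for visual stimulation
#'
#' Describes the display used for retinotopic stimulation: viewing distance,
#' physical screen size, pixel resolution and refresh rate. The defaults
#' correspond to a bore-mounted LCD viewed via a head-coil mirror at 119 cm
#' with a 1440 x 1080 pixel raster refreshed at 100 Hz.
#'
#' @param viewing_distance_cm Distance from eye to screen in cm.
#' @param screen_width_cm,screen_height_cm Physical extent of the active
#'   display area in cm.
#' @param resolution_px Integer pair, horizontal and vertical pixel counts.
#' @param refresh_hz Display refresh rate in Hz.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_to_degrees(c(2.0773, 0), geom)  # ~1 degree horizontally
#' @export
screen_geometry <- function(viewing_distance_cm = 119,
                            screen_width_cm = 52.4,
                            screen_height_cm = 39.3,
                            resolution_px = c(1440L, 1080L),
                            refresh_hz = 100) {
  stopifnot(length(resolution_px) == 2)
  vals <- c(viewing_distance_cm, screen_width_cm, screen_height_cm,
            resolution_px, refresh_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry values must be positive and finite")
  }
  structure(
    list(viewing_distance_cm = viewing_distance_cm,
         screen_width_cm = screen_width_cm,
         screen_height_cm = screen_height_cm,
         resolution_px = as.integer(resolution_px),
         refresh_hz = refresh_hz),
    class = "screen_geometry")
}

#' Convert a screen offset to degrees of visual angle
#'
#' Maps an offset from the screen center to visual angle per axis using
#' `deg = atan(offset_cm / distance_cm)`. Offsets may be given in cm or in
#' pixels (converted through the screen's physical size and resolution).
#'
#' @param offset Numeric pair (x, y), offset from the screen center.
#' @param geometry A [screen_geometry()] object.
#' @param units `"cm"` (default) or `"px"`.
#' @return Numeric pair of visual angles in degrees (x rightward, y upward).
#' @export
pixels_to_degrees <- function(offset, geometry, units = c("cm", "px")) {
  units <- match.arg(units)
  stopifnot(inherits(geometry, "screen_geometry"), length(offset) == 2)
  offset_cm <- if (units == "px") {
    offset * c(geometry$screen_width_cm / geometry$resolution_px[1],
               geometry$screen_height_cm / geometry$resolution_px[2])
  } else {
    offset
  }
  atan(offset_cm / geometry$viewing_distance_cm) * 180 / pi
}

#' Generate a retinotopy aperture movie
#'
#' Builds the binary stimulus-aperture time course for standard travelling-wave
#' retinotopy: a rotating wedge, an expanding (or contracting) ring, or a
#' sweeping bar, sampled on a square visual-field grid at one frame per TR.
#' Each stimulus traverses the field exactly once per period and the movie
#' repeats for `n_cycles` cycles (default timing: 24 s period, 1.5 s TR,
#' 5 cycles, i.e. 16 frames per cycle and 80 frames in total).
#'
#' @param kind `"wedge"`, `"ring"` or `"bar"`.
#' @param field_radius Maximum mapped eccentricity in degrees.
#' @param period_s Stimulus period in seconds; must be an integer multiple of
#'   `tr_s`.
#' @param n_cycles Number of stimulus cycles.
#' @param tr_s Volume repetition time in seconds.
#' @param grid_n Number of grid points per axis spanning `±field_radius`.
#' @param wedge_width_deg Angular width of the wedge in degrees of polar angle.
#' @param ring_duty Ring thickness as a fraction of `field_radius`.
#' @param bar_width Bar width in degrees; defaults to `field_radius / 4`.
#' @param bar_orientation_deg Orientation of the bar's long axis in degrees
#'   (0 = vertical bar sweeping horizontally); the bar moves perpendicular to
#'   its long axis.
#' @param contracting For rings, sweep inward instead of outward.
#' @return An object of class `aperture_movie`: list with `frames` (0/1 array
#'   `grid_n x grid_n x n_frames`), `grid_x`, `grid_y` (degrees), `tr_s`,
#'   `period_s`, `n_cycles`, `kind`.
#' @examples
#' ap <- make_aperture("wedge", field_radius = 10)
#' dim(ap$frames)  # 101 101 80
#' @export
make_aperture <- function(kind = c("wedge", "ring", "bar"),
                          field_radius = 10,
                          period_s = 24,
                          n_cycles = 5,
                          tr_s = 1.5,
                          grid_n = 101,
                          wedge_width_deg = 45,
                          ring_duty = 1 / 8,
                          bar_width = NULL,
                          bar_orientation_deg = 0,
                          contracting = FALSE) {
  kind <- match.arg(kind)
  if (field_radius <= 0) stop("field_radius must be positive")
  fpc <- period_s / tr_s
  if (abs(fpc - round(fpc)) > 1e-9) {
    stop(sprintf("period_s (%g s) must be an integer multiple of tr_s (%g s)",
                 period_s, tr_s))
  }
  fpc <- as.integer(round(fpc))
  n_frames <- fpc * n_cycles
  ax <- seq(-field_radius, field_radius, length.out = grid_n)
  X <- matrix(ax, grid_n, grid_n)
  Y <- matrix(ax, grid_n, grid_n, byrow = TRUE)  # [i, j] = (x_i, y_j)
  ecc <- sqrt(X^2 + Y^2)
  within <- ecc <= field_radius
  if (is.null(bar_width)) bar_width <- field_radius / 4

  cycle <- array(0, dim = c(grid_n, grid_n, fpc))
  for (f in seq_len(fpc)) {
    phase <- (f - 1) / fpc
    mask <- switch(kind,
      wedge = {
        ang0 <- 2 * pi * phase
        d <- atan2(Y, X) - ang0
        d <- abs(((d + pi) %% (2 * pi)) - pi)  # angular distance
        within & (d <= (wedge_width_deg / 2) * pi / 180)
      },
      ring = {
        w <- ring_duty * field_radius
        p <- if (contracting) 1 - phase else phase
        r0 <- p * field_radius
        within & ecc >= r0 & ecc <= r0 + w
      },
      bar = {
        th <- bar_orientation_deg * pi / 180
        # signed distance along the motion axis (perpendicular to bar)
        proj <- X * cos(th) + Y * sin(th)
        pos <- -field_radius + phase * 2 * field_radius + bar_width / 2
        within & abs(proj - pos) <= bar_width / 2
      })
    cycle[, , f] <- mask * 1
  }
  frames <- array(cycle, dim = c(grid_n, grid_n, n_frames))
  for (k in seq_len(n_cycles - 1)) {
    frames[, , k * fpc + seq_len(fpc)] <- cycle
  }
  structure(
    list(frames = frames, grid_x = ax, grid_y = ax,
         tr_s = tr_s, period_s = period_s, n_cycles = n_cycles,
         field_radius = field_radius, kind = kind),
    class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("aperture_movie: %s, %d x %d grid over ±%g°, %d frames (TR %g s, period %g s, %d cycles)\n",
              x$kind, length(x$grid_x), length(x$grid_y), x$field_radius,
              dim(x$frames)[3], x$tr_s, x$period_s, x$n_cycles))
  invisible(x)
}

# frames x pixels design matrix of an aperture movie (column-major pixels)
aperture_matrix <- function(aperture) {
  d <- dim(aperture$frames)
  t(matrix(aperture$frames, d[1] * d[2], d[3]))
}

#' Save / load aperture movies
#'
#' Apertures are written as a flat binary array of 0/1 bytes alongside a JSON
#' sidecar recording the grid axes and timing, so they can be exchanged with
#' other tools.
#'
#' @param aperture An `aperture_movie`.
#' @param path Output path for the data file; the sidecar is `<path>.json`.
#' @return `write_aperture` returns `path` invisibly; `read_aperture` returns
#'   an `aperture_movie`.
#' @export
write_aperture <- function(aperture, path) {
  stopifnot(inherits(aperture, "aperture_movie"))
  writeBin(as.raw(aperture$frames), path)
  meta <- aperture[setdiff(names(aperture), "frames")]
  meta$dim <- dim(aperture$frames)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aperture
#' @export
read_aperture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  frames <- array(as.numeric(readBin(path, "raw", n)), dim = meta$dim)
  structure(
    list(frames = frames, grid_x = meta$grid_x, grid_y = meta$grid_y,
         tr_s = meta$tr_s, period_s = meta$period_s, n_cycles = meta$n_cycles,
         field_radius = meta$field_radius, kind = meta$kind),
    class = "aperture_movie")
}
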