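#' Detector and electron-optics geometry
#'
#' Bundles the parameters needed to map between detector pixels and
#' reciprocal-space vectors: pixel size, effective camera length, electron
#' wavelength (derived from the accelerating voltage unless given
#' explicitly), beam centre, image shape and the azimuth of the goniometer
#' tilt axis in the detector plane.
#'
#' Pixel coordinates are 0-based with `(x, y) = (column, row)` and the
#' origin at the image corner; the beam centre is stored in the same
#' convention.  Angles are degrees in every user-facing argument and are
#' converted to radians internally.
#'
#' @param pixel_size_mm Physical pixel size in mm (default 0.0156, i.e.
#'   15.6 um, a 4k CMOS diffraction camera).
#' @param camera_length_mm Effective camera length in mm.  The default
#'   2000 mm puts roughly 1.6 A resolution at the edge of a 4096-pixel
#'   detector with 15.6 um pixels.
#' @param voltage_kv Accelerating voltage in kV; sets the wavelength unless
#'   `wavelength` is supplied.
#' @param beam_center_px Length-2 numeric `(x, y)` beam centre in pixels
#'   (0-based).  Default: image centre.
#' @param image_shape Length-2 integer `(nx, ny)` detector size in pixels.
#' @param tilt_axis_deg Azimuth of the tilt axis in the detector plane,
#'   degrees anticlockwise from the +x (column) axis.
#' @param wavelength Electron wavelength in Angstrom; overrides
#'   `voltage_kv` when given.
#'
#' @return An object of class `microed_geometry`.
#' @examples
#' geom <- detector_geometry()
#' geom$wavelength  # ~0.0251 A at 200 kV
#' @export
detector_geometry <- function(pixel_size_mm = 0.0156,
                              camera_length_mm = 2000,
                              voltage_kv = 200,
                              beam_center_px = NULL,
                              image_shape = c(4096L, 4096L),
                              tilt_axis_deg = 0,
                              wavelength = NULL) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 2))
  if (pixel_size_mm <= 0 || camera_length_mm <= 0) {
    stop("pixel_size_mm and camera_length_mm must be positive", call. = FALSE)
  }
  if (is.null(wavelength)) wavelength <- electron_wavelength(voltage_kv)
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  if (is.null(beam_center_px)) beam_center_px <- (image_shape - 1) / 2
  if (beam_center_px[1] < 0 || beam_center_px[1] > image_shape[1] - 1 ||
      beam_center_px[2] < 0 || beam_center_px[2] > image_shape[2] - 1) {
    stop("beam_center_px must lie within image_shape", call. = FALSE)
  }
  structure(
    list(pixel_size = pixel_size_mm,
         camera_length = camera_length_mm,
         voltage_kv = voltage_kv,
         wavelength = wavelength,
         beam_center = as.numeric(beam_center_px),
         image_shape = as.integer(image_shape),
         tilt_axis = tilt_axis_deg),
    class = "microed_geometry")
}

#' @export
print.microed_geometry <- function(x, ...) {
  cat("<microed_geometry>\n")
  cat(sprintf("  pixel size    : %.4g mm\n", x$pixel_size))
  cat(sprintf("  camera length : %.6g mm\n", x$camera_length))
  cat(sprintf("  wavelength    : %.6g A (%g kV)\n", x$wavelength, x$voltage_kv))
  cat(sprintf("  image shape   : %d x %d px, beam centre (%.1f, %.1f)\n",
              x$image_shape[1], x$image_shape[2],
              x$beam_center[1], x$beam_center[2]))
  cat(sprintf("  tilt axis     : %g deg from +x\n", x$tilt_axis))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage_kv`
#' kilovolts, with the relativistic correction:
#' lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2))).
#' At 200 kV this evaluates to 0.0251 A (printed as 0.025 A).
#'
#' @param voltage_kv Accelerating voltage in kilovolts (> 0).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(200)
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(!is.finite(voltage_kv)) || any(voltage_kv <= 0)) {
    stop("voltage_kv must be positive and finite", call. = FALSE)
  }
  h <- 6.62607015e-34   # J s
  m0 <- 9.1093837015e-31 # kg
  e <- 1.602176634e-19  # C
  c <- 299792458        # m/s
  v <- voltage_kv * 1e3
  lambda_m <- h / sqrt(2 * m0 * e * v * (1 + e * v / (2 * m0 * c^2)))
  lambda_m * 1e10
}

#' Ewald-sphere offset (sagitta) at a given resolution
#'
#' Distance between the flat zero-tilt reciprocal plane and the Ewald
#' sphere at scattering vector length 1/d: the exact sagitta
#' `1/lambda - sqrt(1/lambda^2 - 1/d^2)`, which agrees with the
#' small-angle approximation `lambda / (2 d^2)` to first order.  For
#' 200 kV electrons (`lambda = 0.025` A) at 2 A resolution the offset is
#' only ~0.003 1/A, the quantitative sense in which the sphere is
#' "nearly flat".
#'
#' @param resolution Resolution d in Angstrom (must exceed the wavelength).
#' @param wavelength Wavelength lambda in Angstrom.
#' @param approximate If `TRUE` return `lambda/(2 d^2)` instead of the
#'   exact form.
#' @return Offset in reciprocal Angstrom (1/A).
#' @examples
#' ewald_offset(2, 0.025)
#' @export
ewald_offset <- function(resolution, wavelength, approximate = FALSE) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  if (any(resolution <= wavelength)) {
    stop("resolution must exceed the wavelength (sphere does not reach)",
         call. = FALSE)
  }
  if (approximate) return(wavelength / (2 * resolution^2))
  1 / wavelength - sqrt(1 / wavelength^2 - 1 / resolution^2)
}

# Rotation by theta (deg) about a unit axis in the detector plane at
# azimuth `axis_deg` from +x (Rodrigues).  Applies to lab-frame vectors.
tilt_rotation <- function(theta_deg, axis_deg = 0) {
  th <- theta_deg * pi / 180
  ph <- axis_deg * pi / 180
  u <- c(cos(ph), sin(ph), 0)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)  # column-major: K %*% v = u x v
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Map detector spots to reciprocal-space vectors
#'
#' Converts detector pixel positions on a frame recorded at a given stage
#' tilt into reciprocal-lattice vectors expressed in the crystal-fixed
#' (zero-tilt) frame.  Under the default flat-Ewald approximation the
#' in-plane components are `(dx * p / (L * lambda), dy * p / (L * lambda))`
#' with `dx, dy` measured in pixels from the beam centre; the vector is
#' then rotated by minus the tilt angle about the tilt axis.  The exact
#' spherical mapping (`mode = "exact"`) places the vector on the Ewald
#' sphere instead.
#'
#' @param xy Numeric length-2 vector or n x 2 matrix / data frame of
#'   0-based pixel coordinates `(x, y)`.
#' @param tilt_angle Stage tilt in degrees (|tilt| < 90).
#' @param geom A [detector_geometry()].
#' @param mode `"flat"` (default) or `"exact"`.
#' @return A tibble with columns `gx, gy, gz` (1/A) in the crystal-fixed
#'   frame, one row per spot.
#' @seealso [reciprocal_to_detector()] for the inverse mapping.
#' @export
spot_to_reciprocal <- function(xy, tilt_angle, geom, mode = c("flat", "exact")) {
  mode <- match.arg(mode)
  xy <- as_xy_matrix(xy)
  if (abs(tilt_angle) >= 90) stop("|tilt_angle| must be < 90 deg", call. = FALSE)
  p <- geom$pixel_size; L <- geom$camera_length; lam <- geom$wavelength
  dx <- (xy[, 1] - geom$beam_center[1]) * p
  dy <- (xy[, 2] - geom$beam_center[2]) * p
  if (mode == "flat") {
    s <- cbind(dx / (L * lam), dy / (L * lam), 0)
  } else {
    nrm <- sqrt(dx^2 + dy^2 + L^2)
    s <- cbind(dx / nrm, dy / nrm, L / nrm - 1) / lam
  }
  R <- tilt_rotation(tilt_angle, geom$tilt_axis)
  g <- s %*% R  # rows: s_i^T R = (R^T s_i)^T, i.e. rotate lab -> crystal
  tibble::tibble(gx = g[, 1], gy = g[, 2], gz = g[, 3])
}

#' Map reciprocal vectors to detector positions
#'
#' Inverse of [spot_to_reciprocal()]: rotates crystal-fixed reciprocal
#' vectors into the lab frame at the given tilt and projects them onto the
#' detector.  Round trips with [spot_to_reciprocal()] to better than 1e-6
#' pixel in both modes.
#'
#' @inheritParams spot_to_reciprocal
#' @param g Length-3 vector, n x 3 matrix, or data frame with columns
#'   `gx, gy, gz` (1/A, crystal-fixed frame).
#' @return A tibble with columns `x, y` (0-based pixels).
#' @export
reciprocal_to_detector <- function(g, tilt_angle, geom,
                                   mode = c("flat", "exact")) {
  mode <- match.arg(mode)
  g <- as_g_matrix(g)
  p <- geom$pixel_size; L <- geom$camera_length; lam <- geom$wavelength
  R <- tilt_rotation(tilt_angle, geom$tilt_axis)
  s <- g %*% t(R)  # crystal -> lab
  if (mode == "flat") {
    x <- geom$beam_center[1] + s[, 1] * L * lam / p
    y <- geom$beam_center[2] + s[, 2] * L * lam / p
  } else {
    kz <- s[, 3] + 1 / lam   # outgoing wavevector z-component
    if (any(kz <= 0)) stop("reflection scatters away from the detector",
                           call. = FALSE)
    x <- geom$beam_center[1] + L * s[, 1] / kz / p
    y <- geom$beam_center[2] + L * s[, 2] / kz / p
  }
  tibble::tibble(x = x, y = y)
}

#' Resolution of a detector spot
#'
#' `d = 1 / |g|` for the reciprocal vector of a spot; decreases
#' monotonically with radial distance from the beam centre.
#'
#' @inheritParams spot_to_reciprocal
#' @return Numeric vector of resolutions in Angstrom.
#' @export
resolution_of_spot <- function(xy, geom, mode = c("flat", "exact")) {
  mode <- match.arg(mode)
  g <- spot_to_reciprocal(xy, 0, geom, mode)
  len <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  if (any(len == 0)) {
    stop("spot at the beam centre has undefined resolution", call. = FALSE)
  }
  1 / len
}

as_xy_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  storage.mode(xy) <- "double"
  xy
}

as_g_matrix <- function(g) {
  if (is.data.frame(g)) g <- as.matrix(g[, c("gx", "gy", "gz")])
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  storage.mode(g) <- "double"
  g
}
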