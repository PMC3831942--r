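#' Electron-dose model
#'
#' Describes the exposure protocol and the radiation-damage response used
#' by the simulator: intensities are unaffected until the cumulative dose
#' reaches `critical_dose`, then decay linearly at `decay_rate` (fractional
#' intensity loss per e-/A^2 beyond the critical dose).
#'
#' Defaults follow the low-dose MicroED protocol: ~0.01 e-/A^2 per second,
#' 10 s exposures, and a critical dose of ~9 e-/A^2 at which decay first
#' becomes apparent.  The linear decay rate beyond the critical dose is a
#' modelling choice (0.1 per e-/A^2 by default).
#'
#' @param dose_rate Dose rate in e-/A^2/s.
#' @param exposure Exposure time per frame in seconds.
#' @param critical_dose Cumulative dose (e-/A^2) at which decay begins;
#'   `Inf` disables decay.
#' @param decay_rate Fractional intensity loss per e-/A^2 beyond the
#'   critical dose (>= 0).
#' @return An object of class `microed_dose`.
#' @export
dose_model <- function(dose_rate = 0.01, exposure = 10,
                       critical_dose = 9, decay_rate = 0.1) {
  if (any(c(dose_rate, exposure, decay_rate) < 0) || critical_dose < 0) {
    stop("dose model parameters must be non-negative", call. = FALSE)
  }
  structure(list(dose_rate = dose_rate, exposure = exposure,
                 critical_dose = critical_dose, decay_rate = decay_rate),
            class = "microed_dose")
}

dose_factor <- function(dose, model) {
  excess <- pmax(0, dose - model$critical_dose)
  pmax(0, 1 - model$decay_rate * excess)
}

#' Desk-scale simulation geometry
#'
#' The full-frame diffraction geometry (4096 px, 15.6 um pixels) binned by
#' an integer factor: same angular coverage and camera length, coarser
#' pixels.  Binning 4 (the default, 1024 px frames) keeps the reference
#' cell's reciprocal-lattice spacing at ~10 px while making whole-series
#' simulations cheap.
#'
#' @param binning Integer binning factor (1 = full frame).
#' @param ... Passed on to [detector_geometry()].
#' @return A [detector_geometry()].
#' @export
sim_geometry <- function(binning = 4, ...) {
  detector_geometry(pixel_size_mm = 0.0156 * binning,
                    image_shape = c(4096L, 4096L) %/% as.integer(binning),
                    ...)
}

#' Random crystal orientation angles
#'
#' Three extrinsic rotation angles (degrees, applied as Rz * Ry * Rx to the
#' zero-tilt reciprocal basis).  Draws are uniform per angle — adequate for
#' orientation-recovery experiments, though not exactly uniform on the
#' rotation group.
#'
#' @param seed Integer seed.
#' @return Numeric length-3 vector of degrees.
#' @export
random_orientation <- function(seed) {
  set.seed(seed)
  c(stats::runif(1, 0, 360), stats::runif(1, -90, 90), stats::runif(1, 0, 360))
}

orientation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Wilson-like ground-truth intensity model
#'
#' Draws one true intensity per symmetry-unique reflection from an
#' exponential distribution whose mean falls off with resolution as
#' `mean_intensity * exp(-b_factor / (2 d^2))` (a Wilson-statistics
#' acentric model with an overall temperature factor).  All Laue 4/mmm
#' equivalents and Friedel mates share the value of their canonical
#' representative.  Systematically absent indices of the cell's space
#' group get `leak_fraction` times the local (resolution-dependent) mean
#' intensity — zero by default, or a small positive fraction to emulate
#' dynamic-scattering leakage into forbidden positions.
#'
#' @param cell A [unit_cell()]; its `space_group` sets the absence rules.
#' @param dmin High-resolution cutoff in Angstrom.
#' @param seed Integer seed; the same seed always returns the same map.
#' @param mean_intensity Mean intensity (counts) at infinite d.
#' @param b_factor Overall temperature factor (A^2).
#' @param leak_fraction Fraction of the local mean intensity assigned to
#'   systematically absent reflections (default 0).
#' @return A tibble of canonical reflections: `h, k, l, d, I, absent`.
#' @export
sample_intensity_model <- function(cell, dmin = 2.9, seed = 1,
                                   mean_intensity = 1500, b_factor = 15,
                                   leak_fraction = 0) {
  stopifnot(dmin > 0)
  uniq <- enumerate_hkl(cell, dmin, unique_only = TRUE)
  absent <- is_systematic_absence(uniq, cell$space_group)
  mu <- mean_intensity * exp(-b_factor / (2 * uniq$d^2))
  set.seed(seed)
  I <- stats::rexp(nrow(uniq), rate = 1 / mu)
  I[absent] <- leak_fraction * mu[absent]
  dplyr::mutate(uniq, I = I, absent = absent)
}

#' Simulate a MicroED tilt series
#'
#' Forward model of still-frame electron-diffraction data collection from
#' a single crystal: the crystal (known cell, known orientation) is tilted
#' in equal steps about the goniometer axis, and on each frame every
#' reflection whose excitation error (distance of the rotated
#' reciprocal-lattice point from the flat Ewald plane) is at most
#' `rocking_half_width` is recorded as a 2D Gaussian spot on a constant
#' background with Poisson noise.  Spot intensity is
#' `true intensity x partiality x dose decay`, with triangular partiality
#' `1 - |zeta| / rho`.  The ground-truth table lists every rendered
#' reflection with its frame, position, partiality and intensity.
#'
#' Frames are rendered lazily: with `render = FALSE` only metadata and the
#' ground-truth table are produced (cheap; sufficient for most property
#' tests), and [render_frames()] fills in images on demand.
#'
#' @param cell A [unit_cell()].
#' @param orientation Three extrinsic rotation angles in degrees (see
#'   [random_orientation()]), or a 3x3 rotation matrix.
#' @param geom A [detector_geometry()]; default [sim_geometry()].
#' @param tilt_start,tilt_stop,tilt_step Tilt protocol in degrees
#'   (default -45 to +45 in 1 deg steps: 91 frames covering a 90 deg
#'   wedge).
#' @param rocking_half_width Half-width rho of the effective rocking
#'   profile in 1/A (default 5e-4, consistent with observed reflection
#'   extents of ~1/1000 1/A).
#' @param dose A [dose_model()].
#' @param dmin,dmax Resolution range of simulated reflections (A).
#' @param intensities Optional tibble from [sample_intensity_model()];
#'   sampled with `seed` when `NULL`.
#' @param seed Seed for the intensity model.
#' @param noise_seed Seed for rendering noise (default `seed + 1`).
#' @param render `TRUE` (render every frame), `FALSE` (none), or an
#'   integer vector of frame indices to render.
#' @param background Constant background level in counts.
#' @param spot_sigma Gaussian spot sigma in pixels (default 1.5, i.e.
#'   FWHM ~3.5 px).
#' @param poisson_noise Apply Poisson noise to rendered frames.
#' @return An object of class `microed_series`: a list with `meta`
#'   (tibble: frame, tilt, exposure, cumulative_dose), `truth` (tibble:
#'   h, k, l, frame, tilt, x, y, zeta, partiality, d, I_true, dose_factor,
#'   I_spot), `frames` (named list of image matrices), plus the geometry,
#'   cell, orientation matrix and parameters.
#' @export
simulate_tilt_series <- function(cell = reference_cell(),
                                 orientation = c(0, 0, 0),
                                 geom = sim_geometry(),
                                 tilt_start = -45, tilt_stop = 45,
                                 tilt_step = 1,
                                 rocking_half_width = 5e-4,
                                 dose = dose_model(),
                                 dmin = 2.9, dmax = 20,
                                 intensities = NULL,
                                 seed = 1, noise_seed = seed + 1,
                                 render = FALSE,
                                 background = 20, spot_sigma = 1.5,
                                 poisson_noise = TRUE) {
  stopifnot(tilt_step > 0, tilt_stop > tilt_start, rocking_half_width > 0)
  tilts <- seq(tilt_start, tilt_stop, by = tilt_step)
  n_frames <- length(tilts)
  if (is.null(intensities)) {
    intensities <- sample_intensity_model(cell, dmin = dmin, seed = seed)
  }
  refl <- enumerate_hkl(cell, dmin, dmax)
  canon <- canonical_hkl(refl)
  refl$I_true <- intensities$I[match(paste(canon$h, canon$k, canon$l),
                                     paste(intensities$h, intensities$k,
                                           intensities$l))]
  refl <- refl[!is.na(refl$I_true), ]

  U <- if (is.matrix(orientation)) orientation else orientation_matrix(orientation)
  B <- basis_matrix(cell_to_basis(cell))
  G0 <- U %*% B %*% t(as_hkl_matrix(refl))   # 3 x N, crystal frame at 0 tilt

  margin <- ceiling(4 * spot_sigma) + 1
  rows <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    R <- tilt_rotation(tilts[i], geom$tilt_axis)
    G <- R %*% G0
    zeta <- G[3, ]
    vis <- abs(zeta) <= rocking_half_width
    if (!any(vis)) next
    xy <- reciprocal_to_detector(t(G[, vis, drop = FALSE]), 0, geom)
    inb <- xy$x >= margin & xy$x <= geom$image_shape[1] - 1 - margin &
      xy$y >= margin & xy$y <= geom$image_shape[2] - 1 - margin
    if (!any(inb)) next
    idx <- which(vis)[inb]
    z <- zeta[idx]
    rows[[i]] <- tibble::tibble(
      h = refl$h[idx], k = refl$k[idx], l = refl$l[idx],
      frame = i, tilt = tilts[i],
      x = xy$x[inb], y = xy$y[inb],
      zeta = z,
      partiality = 1 - abs(z) / rocking_half_width,
      d = refl$d[idx], I_true = refl$I_true[idx])
  }
  truth <- dplyr::bind_rows(rows)
  if (nrow(truth) == 0) {
    warning("empty series: no reflection satisfies the rocking condition ",
            "on any frame", call. = FALSE)
    truth <- tibble::tibble(h = integer(), k = integer(), l = integer(),
                            frame = integer(), tilt = numeric(),
                            x = numeric(), y = numeric(), zeta = numeric(),
                            partiality = numeric(), d = numeric(),
                            I_true = numeric())
  }
  cum_dose <- seq_len(n_frames) * dose$dose_rate * dose$exposure
  truth$dose_factor <- dose_factor(cum_dose[truth$frame], dose)
  truth$I_spot <- truth$I_true * truth$partiality * truth$dose_factor

  series <- structure(
    list(meta = tibble::tibble(frame = seq_len(n_frames), tilt = tilts,
                               exposure = dose$exposure,
                               cumulative_dose = cum_dose),
         truth = truth,
         frames = list(),
         geom = geom, cell = cell, orientation = U, dose = dose,
         params = list(rocking_half_width = rocking_half_width,
                       dmin = dmin, dmax = dmax,
                       background = background, spot_sigma = spot_sigma,
                       poisson_noise = poisson_noise,
                       seed = seed, noise_seed = noise_seed)),
    class = "microed_series")
  if (isTRUE(render)) render <- seq_len(n_frames)
  if (!isFALSE(render) && length(render)) {
    series <- render_frames(series, frames = render)
  }
  series
}

#' @export
print.microed_series <- function(x, ...) {
  cat(sprintf("<microed_series> %d frames, tilt %g..%g deg, %d ground-truth reflections\n",
              nrow(x$meta), min(x$meta$tilt), max(x$meta$tilt), nrow(x$truth)))
  cat(sprintf("  rendered frames: %d; cumulative dose %.3g e-/A^2\n",
              length(x$frames), max(x$meta$cumulative_dose)))
  invisible(x)
}

#' Render frames of a simulated tilt series
#'
#' Draws the diffraction images for the requested frames: constant
#' background plus one isotropic Gaussian per ground-truth reflection
#' (total stamped counts equal to the reflection's `I_spot`), then Poisson
#' noise.  Rendering is per-frame seeded from the series' `noise_seed`, so
#' the result is bit-reproducible and independent of rendering order.
#'
#' @param series A `microed_series`.
#' @param frames Integer frame indices (default: all).
#' @param poisson_noise Override the series' noise setting.
#' @return The series with `frames` filled in (named list, names are frame
#'   indices; matrices indexed `[y + 1, x + 1]` for 0-based pixel (x, y)).
#' @export
render_frames <- function(series, frames = NULL, poisson_noise = NULL) {
  stopifnot(inherits(series, "microed_series"))
  if (is.null(frames)) frames <- series$meta$frame
  if (is.null(poisson_noise)) poisson_noise <- series$params$poisson_noise
  p <- series$params
  nx <- series$geom$image_shape[1]; ny <- series$geom$image_shape[2]
  w <- ceiling(4 * p$spot_sigma)
  for (f in frames) {
    img <- matrix(p$background, nrow = ny, ncol = nx)
    tr <- series$truth[series$truth$frame == f, ]
    for (j in seq_len(nrow(tr))) {
      img <- stamp_gaussian(img, tr$x[j], tr$y[j], tr$I_spot[j],
                            p$spot_sigma, w)
    }
    if (poisson_noise) {
      set.seed((p$noise_seed + f) %% .Machine$integer.max)
      img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                    nrow = ny, ncol = nx)
      storage.mode(img) <- "double"
    }
    series$frames[[as.character(f)]] <- img
  }
  series
}

get_frame <- function(series, frame) {
  key <- as.character(frame)
  if (is.null(series$frames[[key]])) {
    series <- render_frames(series, frames = frame)
  }
  series$frames[[key]]
}

# Add a Gaussian of total volume `total` at fractional 0-based (x0, y0).
stamp_gaussian <- function(img, x0, y0, total, sigma, w) {
  jc <- round(x0); ic <- round(y0)
  js <- max(0, jc - w):min(ncol(img) - 1, jc + w)
  is <- max(0, ic - w):min(nrow(img) - 1, ic + w)
  gx <- exp(-(js - x0)^2 / (2 * sigma^2))
  gy <- exp(-(is - y0)^2 / (2 * sigma^2))
  patch <- (total / (2 * pi * sigma^2)) * outer(gy, gx)
  img[is + 1, js + 1] <- img[is + 1, js + 1] + patch
  img
}

#' Apply (or replace) dose decay on a simulated series
#'
#' Rescales each frame's ground-truth intensities by the decay factor
#' `g(D_k)` for cumulative dose `D_k = k * dose_rate * exposure`: `g = 1`
#' for doses up to the critical dose and a linear decline at `decay_rate`
#' beyond it.  Any already-rendered frames are re-rendered with the same
#' noise seed so images stay consistent with the truth table.
#'
#' @param series A `microed_series`.
#' @param dose A [dose_model()].
#' @return The modified series.
#' @export
apply_dose_decay <- function(series, dose) {
  stopifnot(inherits(series, "microed_series"), inherits(dose, "microed_dose"))
  cum_dose <- series$meta$frame * dose$dose_rate * dose$exposure
  series$meta$cumulative_dose <- cum_dose
  series$meta$exposure <- dose$exposure
  series$dose <- dose
  series$truth$dose_factor <- dose_factor(cum_dose[series$truth$frame], dose)
  series$truth$I_spot <- series$truth$I_true * series$truth$partiality *
    series$truth$dose_factor
  rendered <- as.integer(names(series$frames))
  if (length(rendered)) series <- render_frames(series, frames = rendered)
  series
}
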