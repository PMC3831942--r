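#' Zone normal of a diffraction frame
#'
#' The vector normal to the reciprocal-lattice plane visible on a frame,
#' computed from two reference reflections as `n = r1 x r2` with
#' `r_i = h a* + k b* + l c*`.  Every reflection appearing on the frame
#' satisfies `n . v ~ 0` for its reciprocal vector `v`.
#'
#' @param ref1_hkl,ref2_hkl Miller indices (length-3) of two non-collinear
#'   reference reflections on the frame.
#' @param basis A `microed_basis`.
#' @return Numeric length-3 normal vector (not normalised).
#' @export
frame_normal <- function(ref1_hkl, ref2_hkl, basis) {
  B <- basis_matrix(basis)
  r1 <- as.numeric(B %*% ref1_hkl)
  r2 <- as.numeric(B %*% ref2_hkl)
  n <- c(r1[2] * r2[3] - r1[3] * r2[2],
         r1[3] * r2[1] - r1[1] * r2[3],
         r1[1] * r2[2] - r1[2] * r2[1])
  if (sqrt(sum(n^2)) < 1e-10 * sqrt(sum(r1^2) * sum(r2^2))) {
    stop("reference reflections are collinear; zone normal undefined",
         call. = FALSE)
  }
  n
}

#' Predict the reflections on a frame
#'
#' Enumerates all Miller indices with `d >= dmin` and returns those whose
#' reciprocal vector lies in the zone of the frame normal:
#' `|n_hat . r| / |r| <= threshold`.  The default threshold is the
#' per-reflection bound `2 * rocking_half_width / |r|` (the normalised
#' width of the rocking slab), so low-angle reflections get a wider
#' angular acceptance, as they should.  When the frame's tilt angle and
#' the detector geometry are supplied, predicted detector coordinates are
#' included.
#'
#' @param n Zone normal (length-3), e.g. from [frame_normal()].
#' @param basis A `microed_basis`.
#' @param dmin High-resolution cutoff (A).
#' @param zone_threshold Scalar bound on `|n_hat . r| / |r|`; `NULL`
#'   (default) uses the per-reflection rocking bound.
#' @param rocking_half_width Rocking half-width (1/A) for the default
#'   threshold.
#' @param dmax Low-resolution cutoff (A).
#' @param tilt_angle,geom Optional: frame tilt (deg) and
#'   [detector_geometry()] to compute predicted `x, y`.
#' @return Tibble `h, k, l, d` (plus `x, y` when geometry is given).
#' @export
predict_reflections <- function(n, basis, dmin, zone_threshold = NULL,
                                rocking_half_width = 5e-4, dmax = Inf,
                                tilt_angle = NULL, geom = NULL) {
  if (!is.null(zone_threshold) && zone_threshold <= 0) {
    stop("zone_threshold must be positive", call. = FALSE)
  }
  stopifnot(dmin > 0)
  B <- basis_matrix(basis)
  cell <- cell_from_basis(B)
  refl <- enumerate_hkl(cell, dmin, dmax)
  G <- as_hkl_matrix(refl) %*% t(B)
  glen <- sqrt(rowSums(G^2))
  nhat <- n / sqrt(sum(n^2))
  zone <- abs(G %*% nhat) / glen
  thr <- if (is.null(zone_threshold)) 2 * rocking_half_width / glen
         else zone_threshold
  keep <- as.vector(zone <= thr)
  out <- refl[keep, ]
  if (!is.null(tilt_angle) && !is.null(geom)) {
    xy <- reciprocal_to_detector(G[keep, , drop = FALSE], tilt_angle, geom)
    out$x <- xy$x; out$y <- xy$y
  }
  out
}

#' Integrate a spot with the square/circle mask
#'
#' Centres a square box of half-width `box_half_width` pixels on the
#' reflection; the inscribed circle has diameter equal to the square side.
#' The mean pixel intensity outside the circle but inside the square is
#' the local background; it is subtracted from every in-circle pixel and
#' the residuals summed.  Both masks are point-symmetric about the centre,
#' so any linear background gradient cancels exactly.
#'
#' @param image Numeric matrix (`[y + 1, x + 1]` indexing).
#' @param center_xy Length-2 `(x, y)` in 0-based pixels (rounded to the
#'   nearest pixel for mask placement).
#' @param box_half_width Half-width of the square in pixels (side
#'   `2 w + 1`; default 5, an 11 px box covering 3-5 px FWHM spots).
#' @return Background-subtracted integrated intensity (may be negative on
#'   noise).  Errors if the box crosses the image edge.
#' @export
integrate_spot <- function(image, center_xy, box_half_width = 5) {
  w <- as.integer(box_half_width)
  jc <- round(center_xy[1]); ic <- round(center_xy[2])
  ny <- nrow(image); nx <- ncol(image)
  if (jc - w < 0 || jc + w > nx - 1 || ic - w < 0 || ic + w > ny - 1) {
    stop("integration box crosses the image edge", call. = FALSE)
  }
  off <- -w:w
  patch <- image[ic + off + 1, jc + off + 1]
  r2 <- outer(off^2, off^2, "+")
  in_circle <- r2 <= (w + 0.5)^2
  bg <- mean(patch[!in_circle])
  sum(patch[in_circle] - bg)
}

#' Spot profile FWHM in x, y and across tilts
#'
#' Full width at half maximum of a reflection's intensity profile: the 1D
#' x and y profiles through the maximum pixel on the middle frame, and the
#' z (tilt) profile of the peak pixel across three consecutive frames.
#' Widths are found by linear interpolation of the half-maximum crossings
#' of the background-subtracted profile; a profile that never falls below
#' half maximum on a side gives `NA` with a flag.
#'
#' @param frames List of 3 consecutive frame images (middle = the spot's
#'   frame).
#' @param center_xy `(x, y)` of the spot on the middle frame (0-based).
#' @param half_window Half-width (px) of the profile window.
#' @return Tibble `fwhm_x, fwhm_y, fwhm_z` (px, px, frames) and `flat`
#'   (TRUE when any profile was flat/undefined).
#' @export
spot_profile_fwhm <- function(frames, center_xy, half_window = 6) {
  stopifnot(length(frames) == 3)
  img <- frames[[2]]
  jc <- round(center_xy[1]); ic <- round(center_xy[2])
  w <- half_window
  ny <- nrow(img); nx <- ncol(img)
  jj <- max(0, jc - w):min(nx - 1, jc + w)
  ii <- max(0, ic - w):min(ny - 1, ic + w)
  patch <- img[ii + 1, jj + 1]
  pk <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  icp <- ii[pk[1]]; jcp <- jj[pk[2]]
  px <- img[icp + 1, jj + 1]
  py <- img[ii + 1, jcp + 1]
  pz <- vapply(frames, function(f) f[icp + 1, jcp + 1], numeric(1))
  fx <- profile_fwhm(jj, px)
  fy <- profile_fwhm(ii, py)
  fz <- profile_fwhm(0:2, pz)
  tibble::tibble(fwhm_x = fx, fwhm_y = fy, fwhm_z = fz,
                 flat = anyNA(c(fx, fy, fz)))
}

# FWHM of a sampled 1D profile by interpolated half-max crossings.
profile_fwhm <- function(x, y) {
  bg <- min(y)
  y <- y - bg
  pk <- which.max(y)
  ymax <- y[pk]
  if (ymax <= 0) return(NA_real_)
  half <- ymax / 2
  # single-sample impulse: width of one sample
  left <- NA_real_; right <- NA_real_
  if (pk > 1) {
    below <- which(y[1:(pk - 1)] < half)
    if (length(below)) {
      i <- max(below)
      left <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
    }
  }
  if (pk < length(y)) {
    below <- which(y[(pk + 1):length(y)] < half) + pk
    if (length(below)) {
      i <- min(below)
      right <- x[i] - (half - y[i]) / (y[i - 1] - y[i]) * (x[i] - x[i - 1])
    }
  }
  if (is.na(left) && is.na(right)) return(NA_real_)
  if (is.na(left)) return(2 * (right - x[pk]))
  if (is.na(right)) return(2 * (x[pk] - left))
  right - left
}

#' Predict and integrate every frame of a series
#'
#' The per-frame measurement loop of the processing chain: on each frame,
#' spots are picked and indexed against the basis, the two strongest
#' indexed spots subtending more than 30 degrees at the origin serve as
#' reference reflections for the zone normal, reflections are predicted,
#' and each predicted position is integrated with the square/circle mask.
#' Predictions whose box crosses the frame edge are dropped (flagged in
#' the returned attrition counts).
#'
#' @param series A `microed_series` (frames rendered on demand).
#' @param basis A `microed_basis` (e.g. from [index_tilt_series()]).
#' @param frames Frame indices to process (default: all).
#' @param dmin,dmax Resolution range (A); defaults from the series.
#' @param box_half_width Integration box half-width (px).
#' @param centroid_refine Shift each predicted position to the local
#'   intensity centroid within +/-2 px before integration.
#' @param residual_tol Indexing residual for reference-spot selection.
#' @param threshold Spot-picking threshold for reference spots.
#' @return Tibble of observations: `frame, h, k, l, x, y, intensity, flag`
#'   (`flag` is `"ok"` or `"negative"`).
#' @export
process_frames <- function(series, basis, frames = NULL,
                           dmin = NULL, dmax = NULL, box_half_width = 5,
                           centroid_refine = FALSE, residual_tol = 0.2,
                           threshold = 5) {
  stopifnot(inherits(series, "microed_series"))
  if (is.null(frames)) frames <- series$meta$frame
  if (is.null(dmin)) dmin <- series$params$dmin
  if (is.null(dmax)) dmax <- series$params$dmax
  geom <- series$geom
  rho <- series$params$rocking_half_width
  out <- list()
  n_edge <- 0L
  for (f in frames) {
    img <- get_frame(series, f)
    tilt <- series$meta$tilt[f]
    sp <- pick_spots(img, geom = geom, threshold = threshold, max_spots = 60)
    if (nrow(sp) < 2) next
    G <- as.matrix(spot_to_reciprocal(sp[, c("x", "y")], tilt, geom))
    idx <- index_spots(basis, G, residual_tol = residual_tol)
    ok <- which(idx$indexed & !(idx$h == 0 & idx$k == 0 & idx$l == 0))
    if (length(ok) < 2) next
    refs <- pick_reference_pair(G[ok, , drop = FALSE], sp$intensity[ok])
    if (is.null(refs)) next
    r1 <- c(idx$h[ok[refs[1]]], idx$k[ok[refs[1]]], idx$l[ok[refs[1]]])
    r2 <- c(idx$h[ok[refs[2]]], idx$k[ok[refs[2]]], idx$l[ok[refs[2]]])
    n <- frame_normal(r1, r2, basis)
    pred <- predict_reflections(n, basis, dmin = dmin, dmax = dmax,
                                rocking_half_width = rho,
                                tilt_angle = tilt, geom = geom)
    if (!nrow(pred)) next
    res <- integrate_predictions(img, pred, box_half_width, centroid_refine)
    n_edge <- n_edge + attr(res, "n_edge")
    if (nrow(res)) {
      res$frame <- f
      out[[length(out) + 1]] <- res
    }
  }
  obs <- dplyr::bind_rows(out)
  if (nrow(obs)) {
    obs <- obs[, c("frame", "h", "k", "l", "x", "y", "intensity", "flag")]
  }
  attr(obs, "n_edge_dropped") <- n_edge
  obs
}

# Strongest pair of indexed spots subtending > 30 deg; falls back to the
# widest-angle pair among the top spots.
pick_reference_pair <- function(G, intensity, min_angle = 30) {
  ord <- order(intensity, decreasing = TRUE)
  Un <- G / sqrt(rowSums(G^2))
  lim <- cos(min_angle * pi / 180)
  for (i in seq_along(ord)[-length(ord)]) {
    for (j in (i + 1):length(ord)) {
      if (abs(sum(Un[ord[i], ] * Un[ord[j], ])) < lim) {
        return(c(ord[i], ord[j]))
      }
    }
  }
  NULL
}

integrate_predictions <- function(img, pred, box_half_width, centroid_refine) {
  ny <- nrow(img); nx <- ncol(img)
  w <- box_half_width + if (centroid_refine) 2 else 0
  inb <- round(pred$x) - w >= 0 & round(pred$x) + w <= nx - 1 &
    round(pred$y) - w >= 0 & round(pred$y) + w <= ny - 1
  n_edge <- sum(!inb)
  pred <- pred[inb, ]
  I <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cx <- c(pred$x[i], pred$y[i])
    if (centroid_refine) cx <- local_centroid(img, cx, 2)
    I[i] <- integrate_spot(img, cx, box_half_width)
  }
  out <- tibble::tibble(h = pred$h, k = pred$k, l = pred$l,
                        x = pred$x, y = pred$y, intensity = I,
                        flag = ifelse(I < 0, "negative", "ok"))
  attr(out, "n_edge") <- n_edge
  out
}

local_centroid <- function(img, center_xy, r) {
  jc <- round(center_xy[1]); ic <- round(center_xy[2])
  jj <- (jc - r):(jc + r); ii <- (ic - r):(ic + r)
  p <- img[ii + 1, jj + 1]
  p <- pmax(p - stats::median(p), 0)
  s <- sum(p)
  if (s <= 0) return(center_xy)
  c(sum(t(p) * jj) / s, sum(p * ii) / s)
}
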