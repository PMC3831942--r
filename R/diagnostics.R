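#' Cumulative electron dose
#'
#' `dose_rate x exposure x n_frames`, in e-/A^2.  Linear in every
#' argument: the standard accounting for a still-frame series of equal
#' exposures.
#'
#' @param dose_rate Dose rate in e-/A^2/s.
#' @param exposure Exposure time per frame in seconds.
#' @param n_frames Number of frames.
#' @return Cumulative dose in e-/A^2.
#' @examples
#' cumulative_dose(0.01, 10, 90)  # 9 e-/A^2
#' @export
cumulative_dose <- function(dose_rate, exposure, n_frames) {
  if (any(c(dose_rate, exposure, n_frames) < 0)) {
    stop("all dose arguments must be non-negative", call. = FALSE)
  }
  dose_rate * exposure * n_frames
}

#' Build a dose series from tracked reflections
#'
#' Normalizes each tracked reflection's per-frame intensities by the mean
#' of its first `n_plateau` frames and pools them against cumulative dose.
#'
#' @param dose Numeric vector of cumulative doses (one per frame,
#'   non-decreasing).
#' @param intensity Matrix (frames x reflections) or vector of tracked
#'   intensities.
#' @param n_plateau Frames used for plateau normalization (default 10).
#' @return A tibble of class `microed_dose_series`: `dose, intensity,
#'   reflection`.
#' @export
dose_series <- function(dose, intensity, n_plateau = 10) {
  if (is.null(dim(intensity))) intensity <- matrix(intensity, ncol = 1)
  stopifnot(length(dose) == nrow(intensity), !is.unsorted(dose))
  norm <- sweep(intensity, 2,
                colMeans(intensity[seq_len(min(n_plateau, nrow(intensity))), ,
                                   drop = FALSE]),
                "/")
  n_refl <- ncol(intensity)
  n_dose <- length(dose)
  out <- tibble::tibble(
    dose = rep(dose, n_refl),
    intensity = as.vector(norm),
    reflection = rep(seq_len(n_refl), each = n_dose))
  class(out) <- unique(c("microed_dose_series", class(out)))
  out
}

#' Detect the critical dose of a diffraction series
#'
#' Fits a plateau-then-linear-decline model to normalized intensity versus
#' cumulative dose: `I(D) = a` for `D <= Dc` and `a - b (D - Dc)` beyond,
#' by least squares over a grid of candidate changepoints `Dc` (every
#' observed dose).  The changepoint model is compared with the constant
#' (no-decay) model by BIC; when the constant model wins, no critical dose
#' is reported.
#'
#' @param series A [dose_series()], or a data frame with columns `dose`
#'   and `intensity` (normalized so the plateau is ~1).
#' @return Object of class `microed_dose_fit`: list with `critical_dose`
#'   (e-/A^2, or `NA` when no decay is detected), `decay_rate` (fractional
#'   loss per e-/A^2), `plateau`, `decay_detected`, `bic_decay`,
#'   `bic_null`, `n`, and the pooled `data`.  Has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
critical_dose <- function(series) {
  stopifnot(all(c("dose", "intensity") %in% names(series)))
  df <- series[stats::complete.cases(series[, c("dose", "intensity")]), ]
  n <- nrow(df)
  if (length(unique(df$dose)) < 10) {
    stop("need at least 10 distinct dose points", call. = FALSE)
  }
  D <- df$dose; y <- df$intensity
  rss_null <- sum((y - mean(y))^2)
  cand <- sort(unique(D))
  cand <- cand[cand < max(D)]  # changepoint must leave data on the right
  best <- list(rss = Inf)
  for (dc in cand) {
    x <- pmax(0, D - dc)
    X <- cbind(1, -x)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || cf[2] < 0) next
    r <- y - X %*% cf
    rss <- sum(r^2)
    if (rss < best$rss) best <- list(rss = rss, dc = dc, a = cf[1], b = cf[2])
  }
  # BIC with Gaussian errors: n log(rss/n) + k log(n)
  bic_null <- n * log(rss_null / n) + 1 * log(n)
  bic_decay <- if (is.finite(best$rss)) {
    n * log(best$rss / n) + 3 * log(n)
  } else {
    Inf
  }
  detected <- bic_decay < bic_null
  structure(list(
    critical_dose = if (detected) best$dc else NA_real_,
    decay_rate = if (detected) unname(best$b) else NA_real_,
    plateau = if (detected) unname(best$a) else mean(y),
    decay_detected = detected,
    bic_decay = bic_decay, bic_null = bic_null,
    rss = if (detected) best$rss else rss_null,
    n = n, data = tibble::tibble(dose = D, intensity = y)),
    class = "microed_dose_fit")
}

#' @export
print.microed_dose_fit <- function(x, ...) {
  if (x$decay_detected) {
    cat(sprintf("<microed_dose_fit> critical dose %.3g e-/A^2, decay %.3g per e-/A^2 (n = %d)\n",
                x$critical_dose, x$decay_rate, x$n))
  } else {
    cat(sprintf("<microed_dose_fit> no decay detected (n = %d)\n", x$n))
  }
  invisible(x)
}

#' Systematic-absence intensity ratios
#'
#' Quantifies dynamic-scattering leakage into symmetry-forbidden axial
#' positions.  For each odd-order axial reflection `(2n+1, 0, 0)` along a*
#' (and `(0, 2n+1, 0)` along b*), the absent intensity is compared with
#' the summed intensity of the four comparison reflections
#' `(2n+2, 1, 0)`, `(2n+2, -1, 0)`, `(2n-2, 1, 0)` and `(2n-2, -1, 0)`
#' (indices swapped for the b* axis).  Cases where any comparison
#' reflection is missing are skipped.  The ratio is invariant to uniform
#' scaling of the intensities.
#'
#' @param observations Tibble with columns `h, k, l` and `intensity` (or
#'   `I`): unmerged zero-layer observations or a merged set.  Observations
#'   of the same index are averaged first.
#' @param axis `"a"`, `"b"` or `"both"`.
#' @return List: `mean_pct, sd_pct, max_pct, n` and `table` (per-absence
#'   ratios in percent).  `n = 0` with a message when no axial absence has
#'   all four comparison reflections.
#' @export
absence_ratio <- function(observations, axis = c("both", "a", "b")) {
  axis <- match.arg(axis)
  df <- observations
  if (!"intensity" %in% names(df) && "I" %in% names(df)) {
    df <- dplyr::rename(df, intensity = "I")
  }
  stopifnot(all(c("h", "k", "l", "intensity") %in% names(df)))
  df <- df |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  lookup <- function(h, k, l) {
    i <- which(df$h == h & df$k == k & df$l == l)
    if (length(i)) df$intensity[i[1]] else NA_real_
  }
  one_axis <- function(swap) {
    get <- if (swap) function(p, q) lookup(q, p, 0) else function(p, q) lookup(p, q, 0)
    ax <- if (swap) df[df$h == 0 & df$l == 0 & df$k %% 2 != 0, ]
          else df[df$k == 0 & df$l == 0 & df$h %% 2 != 0, ]
    ord <- if (swap) abs(ax$k) else abs(ax$h)
    purrr::map_dfr(seq_len(nrow(ax)), function(i) {
      m <- ord[i]                 # m = 2n + 1
      nb <- c(get(m + 1, 1), get(m + 1, -1), get(m - 3, 1), get(m - 3, -1))
      if (anyNA(nb) || sum(nb) <= 0) return(NULL)
      tibble::tibble(axis = if (swap) "b" else "a", order = m,
                     I_absent = ax$intensity[i], I_neighbours = sum(nb),
                     ratio_pct = 100 * ax$intensity[i] / sum(nb))
    })
  }
  tab <- dplyr::bind_rows(
    if (axis %in% c("a", "both")) one_axis(FALSE),
    if (axis %in% c("b", "both")) one_axis(TRUE))
  if (is.null(tab) || nrow(tab) == 0) {
    message("no axial absences with a complete comparison quadruple")
    return(list(mean_pct = NA_real_, sd_pct = NA_real_, max_pct = NA_real_,
                n = 0L, table = tibble::tibble()))
  }
  list(mean_pct = mean(tab$ratio_pct),
       sd_pct = stats::sd(tab$ratio_pct),
       max_pct = max(tab$ratio_pct),
       n = nrow(tab), table = tab)
}

#' Best attainable resolution per frame
#'
#' For each frame, picks spots above the detection threshold and reports
#' the minimum d-spacing among them — the per-tilt attainable resolution.
#' Thin, well-ordered crystals give a flat curve across the whole tilt
#' range; attenuation of high-angle intensities with tilt (an effectively
#' thicker crystal path) makes the curve worsen away from zero tilt.
#'
#' @param series A `microed_series`.
#' @param frames Frames to analyse (default: all rendered, else all).
#' @param threshold Spot-picking threshold (sigma over background).
#' @return Tibble `frame, tilt, n_spots, best_d` (`best_d` is `NA` on
#'   spotless frames).
#' @export
max_resolution_per_frame <- function(series, frames = NULL, threshold = 5) {
  stopifnot(inherits(series, "microed_series"))
  if (is.null(frames)) {
    frames <- if (length(series$frames)) {
      as.integer(names(series$frames))
    } else {
      series$meta$frame
    }
  }
  purrr::map_dfr(frames, function(f) {
    img <- get_frame(series, f)
    sp <- pick_spots(img, geom = series$geom, threshold = threshold)
    best <- if (nrow(sp)) {
      min(resolution_of_spot(sp[, c("x", "y")], series$geom))
    } else {
      NA_real_
    }
    tibble::tibble(frame = f, tilt = series$meta$tilt[f],
                   n_spots = nrow(sp), best_d = best)
  })
}
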