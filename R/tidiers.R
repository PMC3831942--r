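#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a critical-dose fit
#'
#' @param x A `microed_dose_fit` from [critical_dose()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`critical_dose`,
#'   `decay_rate`, `plateau`) and its estimate.
#' @export
tidy.microed_dose_fit <- function(x, ...) {
  tibble::tibble(
    term = c("critical_dose", "decay_rate", "plateau"),
    estimate = c(x$critical_dose, x$decay_rate, x$plateau))
}

#' Glance at a critical-dose fit
#'
#' @inheritParams tidy.microed_dose_fit
#' @return One-row tibble: `decay_detected, critical_dose, decay_rate,
#'   rss, bic_decay, bic_null, nobs`.
#' @export
glance.microed_dose_fit <- function(x, ...) {
  tibble::tibble(decay_detected = x$decay_detected,
                 critical_dose = x$critical_dose,
                 decay_rate = x$decay_rate,
                 rss = x$rss, bic_decay = x$bic_decay,
                 bic_null = x$bic_null, nobs = x$n)
}

#' Glance at a merged reflection set
#'
#' @param x A `microed_merged`.
#' @param dmax,dmin Resolution range for the completeness calculation.
#' @param ... Unused.
#' @return One-row tibble: `n_unique, n_obs, multiplicity, completeness`
#'   (completeness is `NA` when no cell is attached).
#' @export
glance.microed_merged <- function(x, dmax = 20, dmin = 2.9, ...) {
  cell <- attr(x, "cell")
  comp <- if (is.null(cell)) NA_real_ else {
    completeness_stats(x, cell = cell, dmax = dmax, dmin = dmin)$completeness
  }
  tibble::tibble(n_unique = nrow(x),
                 n_obs = attr(x, "n_obs_total"),
                 multiplicity = attr(x, "n_obs_total") / max(1, nrow(x)),
                 completeness = comp)
}
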