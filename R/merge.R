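#' Merge observations by the maximum-intensity rule
#'
#' Groups observations by their canonical Laue 4/mmm representative
#' (point group 422 plus Friedel inversion) and keeps, for each group, the
#' single maximum intensity across all frames and datasets; all other
#' observations are presumed partial and discarded.  Because every merged
#' intensity then stems from one observation, the uncertainties are
#' estimated as `SigI = sqrt(I)` and, after amplitude conversion,
#' `SigF = sqrt(F)`.  No inter-dataset scaling is applied before taking
#' the maximum; the rule implicitly assumes a common scale across the
#' input datasets.
#'
#' @param observations Tibble with columns `h, k, l, intensity` (extra
#'   columns such as `frame` or `dataset` are counted but not otherwise
#'   used).  Typically the output of [process_frames()], possibly
#'   row-bound over several crystals.
#' @param cell Optional [unit_cell()] recorded in the result (used by
#'   [completeness_stats()] and the file writer).
#' @param wavelength Optional wavelength (A) for the file header.
#' @return A `microed_merged` tibble: `h, k, l, I, SigI, F, SigF, n_obs`,
#'   one row per unique reflection (canonical indices), sorted; negative
#'   merged intensities are kept in `I` but clamp to `F = 0` with
#'   `flag = "negative"`.
#' @export
merge_max <- function(observations, cell = NULL, wavelength = NULL) {
  cols <- c("h", "k", "l", "intensity")
  if (!all(cols %in% names(observations))) {
    # allow pre-merged sets (I column) to be re-merged
    if (all(c("h", "k", "l", "I") %in% names(observations))) {
      observations <- dplyr::rename(observations, intensity = "I")
    } else {
      stop("observations need columns h, k, l, intensity", call. = FALSE)
    }
  }
  obs <- observations[!(observations$h == 0 & observations$k == 0 &
                          observations$l == 0), ]
  if (nrow(obs) == 0) {
    merged <- tibble::tibble(h = integer(), k = integer(), l = integer(),
                             I = numeric(), SigI = numeric(), F = numeric(),
                             SigF = numeric(), n_obs = integer(),
                             flag = character())
    return(new_merged(merged, n_obs_total = 0L, cell = cell,
                      wavelength = wavelength))
  }
  canon <- canonical_hkl(obs)
  obs$h <- canon$h; obs$k <- canon$k; obs$l <- canon$l
  merged <- obs |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(I = max(.data$intensity), n_obs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$h, .data$k, .data$l)
  amp <- to_amplitudes(merged$I)
  merged <- dplyr::mutate(merged,
                          SigI = amp$SigI, F = amp$F, SigF = amp$SigF,
                          flag = amp$flag)
  merged <- merged[, c("h", "k", "l", "I", "SigI", "F", "SigF", "n_obs",
                       "flag")]
  new_merged(merged, n_obs_total = nrow(obs), cell = cell,
             wavelength = wavelength)
}

new_merged <- function(df, n_obs_total, cell = NULL, wavelength = NULL) {
  structure(df,
            class = unique(c("microed_merged", class(tibble::tibble()))),
            n_obs_total = n_obs_total,
            cell = cell, wavelength = wavelength)
}

#' @export
print.microed_merged <- function(x, ...) {
  cat(sprintf("<microed_merged> %d unique reflections, %d observations (multiplicity %.3g)\n",
              nrow(x), attr(x, "n_obs_total"),
              attr(x, "n_obs_total") / max(1, nrow(x))))
  NextMethod()
}

#' Convert intensities to structure-factor amplitudes
#'
#' `F = sqrt(max(I, 0))` under the approximation that the measured
#' intensity is the squared amplitude, with `SigI = sqrt(max(I, 0))` and
#' `SigF = sqrt(F)`.  Negative intensities (possible on weak reflections
#' after background subtraction) are flagged and clamped to `F = 0`.
#'
#' @param I Numeric intensities.
#' @param SigI Optional; recomputed as `sqrt(max(I, 0))` when `NULL`.
#' @return Tibble `F, SigF, SigI, flag`.
#' @examples
#' to_amplitudes(16)  # F = 4, SigI = 4, SigF = 2
#' @export
to_amplitudes <- function(I, SigI = NULL) {
  Ic <- pmax(I, 0)
  Fv <- sqrt(Ic)
  if (is.null(SigI)) SigI <- sqrt(Ic)
  tibble::tibble(F = Fv, SigF = sqrt(Fv), SigI = SigI,
                 flag = ifelse(I < 0, "negative", "ok"))
}

#' Completeness, shell table and multiplicity
#'
#' Compares the merged unique reflections against the theoretical unique
#' count: a brute-force enumeration of all Miller indices with
#' `dmin <= d <= dmax` mapped to canonical Laue 4/mmm representatives.
#' When `use_space_group = TRUE` the systematically absent classes of the
#' cell's space group are excluded from the theoretical count (observed
#' data cannot contain them).  The shell table uses shells of equal
#' reciprocal volume (equal width in 1/d^3).
#'
#' @param merged A `microed_merged` (or any tibble with `h, k, l` and
#'   optionally `n_obs`).
#' @param cell A [unit_cell()]; defaults to the one stored in `merged`.
#' @param dmax,dmin Resolution range in Angstrom (defaults 20 and 2.9).
#' @param n_shells Number of resolution shells.
#' @param use_space_group Exclude the space group's systematic absences
#'   from the theoretical count.
#' @return List: `completeness` (fraction), `n_unique_observed`,
#'   `n_unique_theoretical`, `multiplicity`, `shells` (tibble
#'   `d_high, d_low, n_obs, n_theory, completeness`).
#' @export
completeness_stats <- function(merged, cell = NULL, dmax = 20, dmin = 2.9,
                               n_shells = 10, use_space_group = FALSE) {
  stopifnot(dmax > dmin)
  if (is.null(cell)) cell <- attr(merged, "cell")
  if (is.null(cell)) stop("a unit cell is required", call. = FALSE)
  theo <- enumerate_hkl(cell, dmin, dmax, unique_only = TRUE,
                        drop_absent = use_space_group)
  obs <- canonical_hkl(merged)
  obs$d <- d_spacing(cell, obs)
  obs <- dplyr::distinct(obs, .data$h, .data$k, .data$l, .keep_all = TRUE)
  obs <- obs[obs$d >= dmin & obs$d <= dmax, ]
  key <- function(df) paste(df$h, df$k, df$l)
  in_theo <- key(obs) %in% key(theo)
  n_obs_u <- sum(in_theo)
  # equal reciprocal-volume shells
  s3 <- seq(1 / dmax^3, 1 / dmin^3, length.out = n_shells + 1)
  edges <- 1 / s3^(1 / 3)
  shell_of <- function(d) pmin(n_shells, findInterval(1 / d^3, s3,
                                                      rightmost.closed = TRUE))
  sh_obs <- tabulate(shell_of(obs$d[in_theo]), nbins = n_shells)
  sh_theo <- tabulate(shell_of(theo$d), nbins = n_shells)
  shells <- tibble::tibble(
    d_high = edges[-1], d_low = edges[-(n_shells + 1)],
    n_obs = sh_obs, n_theory = sh_theo,
    completeness = ifelse(sh_theo > 0, sh_obs / sh_theo, NA_real_))
  n_tot <- attr(merged, "n_obs_total")
  if (is.null(n_tot)) {
    n_tot <- if ("n_obs" %in% names(merged)) sum(merged$n_obs) else nrow(merged)
  }
  list(completeness = n_obs_u / nrow(theo),
       n_unique_observed = n_obs_u,
       n_unique_theoretical = nrow(theo),
       multiplicity = n_tot / max(1, n_obs_u),
       shells = shells)
}

#' Write a merged set as a plain-text structure-factor file
#'
#' Whitespace-delimited table with exactly the columns
#' `h k l F SIGF I SIGI`, preceded by commented header lines carrying the
#' unit cell, symmetry label, wavelength and resolution range.  Values are
#' written with full precision so that [read_sf_file()] round-trips
#' exactly.
#'
#' @param merged A `microed_merged`.
#' @param path Output file path.
#' @param cell,wavelength Override the values stored in `merged`.
#' @return `path`, invisibly.
#' @export
write_sf_file <- function(merged, path, cell = NULL, wavelength = NULL) {
  if (is.null(cell)) cell <- attr(merged, "cell")
  if (is.null(wavelength)) wavelength <- attr(merged, "wavelength")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# MicroED structure-factor file",
    "# pixel convention: 0-based (x, y) = (column, row), origin at image corner",
    if (!is.null(cell)) sprintf(
      "# cell %.6g %.6g %.6g %.6g %.6g %.6g",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    if (!is.null(cell)) sprintf("# symmetry %s", cell$space_group),
    if (!is.null(wavelength)) sprintf("# wavelength %.6g", wavelength),
    if (nrow(merged)) sprintf("# resolution %.6g %.6g",
                              max_d(merged, cell), min_d(merged, cell)),
    "# columns h k l F SIGF I SIGI",
    "h k l F SIGF I SIGI"), con)
  if (nrow(merged)) {
    rows <- sprintf("%d %d %d %.17g %.17g %.17g %.17g",
                    merged$h, merged$k, merged$l,
                    merged$F, merged$SigF, merged$I, merged$SigI)
    writeLines(rows, con)
  }
  invisible(path)
}

max_d <- function(merged, cell) {
  if (is.null(cell)) return(NA_real_)
  max(d_spacing(cell, merged))
}
min_d <- function(merged, cell) {
  if (is.null(cell)) return(NA_real_)
  min(d_spacing(cell, merged))
}

#' Read a structure-factor file written by [write_sf_file()]
#'
#' @param path File path.
#' @return A `microed_merged` tibble (columns `h, k, l, I, SigI, F, SigF,
#'   n_obs, flag`); the header's cell, symmetry and wavelength are
#'   restored as attributes.
#' @export
read_sf_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  cell <- NULL; wl <- NULL; sg <- "P1"
  for (ln in lines[hdr]) {
    if (grepl("^# cell ", ln)) {
      v <- as.numeric(strsplit(trimws(sub("^# cell", "", ln)), "\\s+")[[1]])
      cell <- v
    } else if (grepl("^# symmetry ", ln)) {
      sg <- trimws(sub("^# symmetry", "", ln))
    } else if (grepl("^# wavelength ", ln)) {
      wl <- as.numeric(trimws(sub("^# wavelength", "", ln)))
    }
  }
  cellobj <- if (!is.null(cell)) {
    unit_cell(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
              space_group = sg)
  }
  body <- which(!hdr)
  if (!length(body)) stop("no data section in ", path, call. = FALSE)
  header_row <- body[1]
  expected <- "h k l F SIGF I SIGI"
  if (trimws(lines[header_row]) != expected) {
    stop(sprintf("line %d: expected column header '%s'", header_row, expected),
         call. = FALSE)
  }
  rows <- body[-1]
  rows <- rows[nzchar(trimws(lines[rows]))]
  parse_row <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 7 || anyNA(v)) {
      stop(sprintf("malformed structure-factor row at line %d", i),
           call. = FALSE)
    }
    v
  }
  m <- t(vapply(rows, parse_row, numeric(7)))
  df <- tibble::tibble(
    h = as.integer(m[, 1]), k = as.integer(m[, 2]), l = as.integer(m[, 3]),
    I = m[, 6], SigI = m[, 7], F = m[, 4], SigF = m[, 5],
    n_obs = 1L, flag = ifelse(m[, 6] < 0, "negative", "ok"))
  new_merged(df, n_obs_total = nrow(df), cell = cellobj, wavelength = wl)
}

#' Dataset perturbations for model-bias validation
#'
#' The four control perturbations used to test whether a structure
#' solution is biased by the search model rather than supported by the
#' measured intensities:
#' \describe{
#'   \item{mode 1}{replace every intensity with a uniform draw between the
#'     minimum and maximum observed intensity;}
#'   \item{mode 2}{randomly permute the intensities over the Miller
#'     indices (the intensity multiset is preserved);}
#'   \item{mode 3}{replace the intensities with donor values measured on
#'     an unrelated structure (recycled cyclically if shorter);}
#'   \item{mode 4}{scale each intensity by a random factor within +/-35%.}
#' }
#' The Miller index set is unchanged in modes 1, 3 and 4; amplitudes and
#' uncertainties are recomputed from the perturbed intensities.
#'
#' @param merged A `microed_merged`.
#' @param mode Integer 1-4.
#' @param seed Integer seed.
#' @param donor_intensities Numeric vector, required for mode 3.
#' @return A `microed_merged` with perturbed intensities.
#' @export
perturb_dataset <- function(merged, mode, seed = 1,
                            donor_intensities = NULL) {
  if (!mode %in% 1:4) stop("mode must be 1, 2, 3 or 4", call. = FALSE)
  set.seed(seed)
  I <- merged$I
  n <- length(I)
  newI <- switch(mode,
    stats::runif(n, min(I), max(I)),
    sample(I, n, replace = FALSE),
    {
      if (is.null(donor_intensities)) {
        stop("mode 3 requires donor_intensities", call. = FALSE)
      }
      rep_len(donor_intensities, n)
    },
    I * (1 + stats::runif(n, -0.35, 0.35)))
  amp <- to_amplitudes(newI)
  out <- merged
  out$I <- newI
  out$SigI <- amp$SigI; out$F <- amp$F; out$SigF <- amp$SigF
  out$flag <- amp$flag
  out
}
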