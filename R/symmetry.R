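# Laue symmetry 4/mmm: point group 422 plus Friedel inversion (16 ops).
# Operator matrices act on column Miller indices (h, k, l).

laue_422_generators <- function() {
  list(
    # four-fold about c: (h,k,l) -> (-k, h, l)
    matrix(c(0, 1, 0,  -1, 0, 0,  0, 0, 1), 3, 3),
    # two-fold about a: (h,k,l) -> (h, -k, -l)
    matrix(c(1, 0, 0,  0, -1, 0,  0, 0, -1), 3, 3)
  )
}

# Group closure from the generators, plus -I (Friedel); cached.
laue_ops_env <- new.env(parent = emptyenv())

laue_operators <- function() {
  if (!is.null(laue_ops_env$ops)) return(laue_ops_env$ops)
  ops <- list(diag(3))
  key <- function(m) paste(as.integer(m), collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- ops
  gens <- laue_422_generators()
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      nm <- g %*% m
      k <- key(nm)
      if (is.null(seen[[k]])) {
        assign(k, TRUE, envir = seen)
        ops <- c(ops, list(nm))
        queue <- c(queue, list(nm))
      }
    }
  }
  ops <- c(ops, lapply(ops, function(m) -m))  # Friedel inversion
  stopifnot(length(ops) == 16L)
  laue_ops_env$ops <- ops
  ops
}

#' Symmetry-equivalent reflections in Laue class 4/mmm
#'
#' Orbit of a Miller index under the 16 operators of Laue class 4/mmm
#' (point group 422 plus Friedel inversion), deduplicated.  This is the
#' grouping used when merging tetragonal data "in P422": equivalents and
#' Friedel mates share one merged intensity.
#'
#' @param hkl Length-3 integer vector (not (0,0,0)).
#' @return A tibble with columns `h, k, l`, one row per distinct
#'   equivalent, sorted; the canonical representative is given by
#'   [canonical_hkl()].
#' @examples
#' laue_equivalents(c(1, 0, 0))  # 4 equivalents
#' laue_equivalents(c(1, 2, 3))  # general position: 16
#' @export
laue_equivalents <- function(hkl) {
  stopifnot(length(hkl) == 3)
  if (all(hkl == 0)) stop("hkl must not be (0,0,0)", call. = FALSE)
  orb <- vapply(laue_operators(), function(m) as.numeric(m %*% hkl),
                numeric(3))
  orb <- unique(t(orb))
  orb <- orb[order(orb[, 1], orb[, 2], orb[, 3]), , drop = FALSE]
  tibble::tibble(h = orb[, 1], k = orb[, 2], l = orb[, 3])
}

#' Canonical (asymmetric-unit) representative of reflections
#'
#' Maps each Miller index to the lexicographically largest orbit member
#' satisfying `h >= k >= 0, l >= 0` — the asymmetric-unit convention for
#' Laue class 4/mmm used by the merging and completeness routines.
#'
#' @param hkl Length-3 vector or n x 3 matrix / data frame with columns
#'   `h, k, l`.
#' @return A tibble with integer columns `h, k, l`, one row per input.
#' @export
canonical_hkl <- function(hkl) {
  H <- as_hkl_matrix(hkl)
  n <- nrow(H)
  best_key <- rep(-Inf, n)
  best <- matrix(0, n, 3)
  for (m in laue_operators()) {
    cand <- H %*% t(m)
    ok <- cand[, 1] >= cand[, 2] & cand[, 2] >= 0 & cand[, 3] >= 0
    key <- cand[, 1] * 4194304 + cand[, 2] * 2048 + cand[, 3]
    key[!ok] <- -Inf
    upd <- key > best_key
    if (any(upd)) {
      best[upd, ] <- cand[upd, , drop = FALSE]
      best_key[upd] <- key[upd]
    }
  }
  tibble::tibble(h = as.integer(round(best[, 1])),
                 k = as.integer(round(best[, 2])),
                 l = as.integer(round(best[, 3])))
}

#' Systematic absences
#'
#' Reflection classes forced to zero intensity by the translational
#' symmetry elements of the space group.  For P4(3)2(1)2 the 2(1) screw
#' axes along a and b make (h,0,0) with odd h and (0,k,0) with odd k
#' absent, and the 4(3) screw along c makes (0,0,l) absent unless l is a
#' multiple of 4.  Space groups without translational elements (e.g.
#' "P422", "P1") have no absences.
#'
#' @param hkl Length-3 vector or n x 3 matrix / data frame.
#' @param space_group Space-group label; `"P43212"` (and the enantiomorph
#'   `"P41212"`) are supported, as are absence-free labels.
#' @return Logical vector.
#' @export
is_systematic_absence <- function(hkl, space_group = "P43212") {
  H <- as_hkl_matrix(hkl)
  sg <- gsub("[^A-Za-z0-9]", "", space_group)
  if (sg %in% c("P43212", "P41212")) {
    (H[, 2] == 0 & H[, 3] == 0 & H[, 1] %% 2 != 0) |
      (H[, 1] == 0 & H[, 3] == 0 & H[, 2] %% 2 != 0) |
      (H[, 1] == 0 & H[, 2] == 0 & H[, 3] %% 4 != 0)
  } else if (sg %in% c("P422", "P4", "P1")) {
    rep(FALSE, nrow(H))
  } else {
    stop("unsupported space group label: ", space_group, call. = FALSE)
  }
}

#' Enumerate reflections in a resolution range
#'
#' All Miller indices (excluding (0,0,0)) with d-spacing in
#' `[dmin, dmax]` for the given cell.
#'
#' @param cell A [unit_cell()].
#' @param dmin,dmax Resolution limits in Angstrom.
#' @param unique_only If `TRUE`, return only canonical asymmetric-unit
#'   representatives (Laue 4/mmm).
#' @param drop_absent If `TRUE`, remove systematic absences of
#'   `cell$space_group`.
#' @return A tibble with columns `h, k, l, d`.
#' @export
enumerate_hkl <- function(cell, dmin, dmax = Inf, unique_only = FALSE,
                          drop_absent = FALSE) {
  stopifnot(dmin > 0, dmax > dmin)
  hmax <- ceiling(cell$a / dmin); kmax <- ceiling(cell$b / dmin)
  lmax <- ceiling(cell$c / dmin)
  if (unique_only) {
    g <- expand.grid(h = 0:hmax, k = 0:kmax, l = 0:lmax)
    g <- g[g$h >= g$k, ]
  } else {
    g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  }
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  d <- d_spacing(cell, g)
  keep <- d >= dmin & d <= dmax
  g <- g[keep, ]; d <- d[keep]
  if (drop_absent) {
    ab <- is_systematic_absence(g, cell$space_group)
    g <- g[!ab, ]; d <- d[!ab]
  }
  out <- tibble::tibble(h = as.integer(g$h), k = as.integer(g$k),
                        l = as.integer(g$l), d = d)
  dplyr::arrange(out, dplyr::desc(.data$d), .data$h, .data$k, .data$l)
}
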