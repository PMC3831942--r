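#' Pick diffraction spots on a frame
#'
#' Finds local maxima above `threshold` robust standard deviations over the
#' background (median / MAD over the whole image), excludes a disc around
#' the beam centre and a border margin, refines each maximum to the
#' background-subtracted 3x3 intensity centroid, and returns at most
#' `max_spots` spots sorted by decreasing peak intensity.
#'
#' @param image Numeric matrix, indexed `[y + 1, x + 1]` (0-based pixel
#'   coordinates `(x, y)` = (column, row)).
#' @param geom Optional [detector_geometry()]; supplies the beam centre
#'   (image centre when `NULL`).
#' @param threshold Detection threshold in robust sigma above background.
#' @param max_spots Maximum number of spots returned.
#' @param exclude_center_px Radius (px) around the beam centre to ignore.
#' @param border Margin (px) at the image edge to ignore.
#' @return Tibble `x, y, intensity` (0-based pixel coordinates); zero rows
#'   when nothing exceeds the threshold.
#' @export
pick_spots <- function(image, geom = NULL, threshold = 5, max_spots = 350,
                       exclude_center_px = 12, border = 8) {
  stopifnot(is.matrix(image))
  bg <- stats::median(image)
  sig <- stats::mad(image)
  if (sig == 0) sig <- max(stats::sd(image), .Machine$double.eps)
  cut <- bg + threshold * sig
  ny <- nrow(image); nx <- ncol(image)
  core <- image[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > cut &
    core >= image[1:(ny - 2), 2:(nx - 1)] & core >= image[3:ny, 2:(nx - 1)] &
    core >= image[2:(ny - 1), 1:(nx - 2)] & core >= image[2:(ny - 1), 3:nx] &
    core >= image[1:(ny - 2), 1:(nx - 2)] & core >= image[1:(ny - 2), 3:nx] &
    core >= image[3:ny, 1:(nx - 2)] & core >= image[3:ny, 3:nx]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }
  y <- idx[, 1]      # 0-based row of the maximum (core offset +1 cancels)
  x <- idx[, 2]
  centre <- if (is.null(geom)) c((nx - 1) / 2, (ny - 1) / 2) else geom$beam_center
  keep <- sqrt((x - centre[1])^2 + (y - centre[2])^2) > exclude_center_px &
    x >= border & x <= nx - 1 - border & y >= border & y <= ny - 1 - border
  x <- x[keep]; y <- y[keep]
  if (!length(x)) {
    return(tibble::tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }
  peak <- image[cbind(y + 1, x + 1)]
  # reject single-pixel outliers: a real spot (FWHM of a few pixels) must
  # also clear the threshold on its background-subtracted 3x3 sum, whose
  # noise scale is 3 sigma
  box_sig <- vapply(seq_along(x), function(i) {
    sum(image[(y[i]:(y[i] + 2)), (x[i]:(x[i] + 2))] - bg)
  }, numeric(1))
  keep <- box_sig >= threshold * 3 * sig
  x <- x[keep]; y <- y[keep]; peak <- peak[keep]
  if (!length(x)) {
    return(tibble::tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }
  ord <- order(peak, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), max_spots))]
  x <- x[ord]; y <- y[ord]; peak <- peak[ord]
  # 3x3 background-subtracted centroid refinement
  xr <- yr <- numeric(length(x))
  for (i in seq_along(x)) {
    jj <- (x[i] - 1):(x[i] + 1); ii <- (y[i] - 1):(y[i] + 1)
    p <- pmax(image[ii + 1, jj + 1] - bg, 0)
    s <- sum(p)
    if (s > 0) {
      xr[i] <- sum(t(p) * jj) / s
      yr[i] <- sum(p * ii) / s
    } else {
      xr[i] <- x[i]; yr[i] <- y[i]
    }
  }
  tibble::tibble(x = xr, y = yr, intensity = peak - bg)
}

#' All pairwise difference vectors
#'
#' Difference vectors between reciprocal-space spot vectors.  On a perfect
#' lattice the differences are themselves lattice vectors, so short
#' differences cluster at plus/minus the reciprocal basis vectors and
#' their sums — the raw material for cell determination.
#'
#' @param g Matrix or tibble of spot vectors (`gx, gy, gz`, 1/A).
#' @param max_length Optional cap: only differences at most this long
#'   (1/A) are returned.
#' @return Tibble `gx, gy, gz, length`.
#' @export
difference_vectors <- function(g, max_length = NULL) {
  G <- as_g_matrix(g)
  n <- nrow(G)
  if (n < 2) stop("need at least 2 spot vectors", call. = FALSE)
  pr <- utils::combn(n, 2)
  D <- G[pr[1, ], , drop = FALSE] - G[pr[2, ], , drop = FALSE]
  len <- sqrt(rowSums(D^2))
  if (!is.null(max_length)) {
    keep <- len <= max_length
    D <- D[keep, , drop = FALSE]; len <- len[keep]
  }
  tibble::tibble(gx = D[, 1], gy = D[, 2], gz = D[, 3], length = len)
}

#' Estimate reciprocal cell lengths from difference vectors
#'
#' Density-based peak picking on the distribution of short difference
#' lengths, replacing the manual measurement of lattice spacings on major
#' zone images.  Because the reciprocal basis vectors are the shortest
#' lattice differences, the estimates are the `n_peaks` *shortest*
#' significant peaks of the length density — not the tallest, since sums
#' and harmonics of the basis vectors are more numerous than the basis
#' vectors themselves.  Diagonal/harmonic peaks that slip in are resolved
#' later by the consistency scoring of [orthogonal_triplets()].
#'
#' @param diffs Output of [difference_vectors()], or a numeric vector of
#'   lengths (1/A).
#' @param n_peaks Number of peak positions to return.
#' @param max_length Only lengths up to this value are considered
#'   (default 0.05 1/A, suited to protein-sized cells of 20 A and up).
#' @param min_length Lengths below this value (1/A) are discarded first;
#'   near-zero differences are re-observations of the same reflection on
#'   neighbouring frames, not lattice vectors.
#' @param bw Kernel bandwidth (1/A); default adapts to the data.
#' @param min_height Peaks below this fraction of the tallest peak are
#'   ignored as noise.
#' @return Numeric vector of up to `n_peaks` peak lengths (1/A), sorted
#'   ascending.
#' @export
estimate_basis_lengths <- function(diffs, n_peaks = 4, max_length = 0.05,
                                   min_length = 0.004, bw = NULL,
                                   min_height = 0.05) {
  len <- if (is.numeric(diffs)) diffs else diffs$length
  len <- len[len >= min_length & len <= max_length]
  if (length(len) < 10) stop("too few short difference vectors", call. = FALSE)
  if (is.null(bw)) bw <- 0.02 * stats::median(len)
  dens <- stats::density(len, bw = bw, n = 2048, from = 0, to = max_length)
  y <- dens$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= min_height * max(y[pk])]
  if (!length(pk)) stop("no density peaks found", call. = FALSE)
  pk <- sort(pk)  # ascending length; basis vectors are the shortest peaks
  sort(dens$x[pk[seq_len(min(n_peaks, length(pk)))]])
}

#' Candidate reciprocal basis vectors from difference vectors
#'
#' Computes all pairwise difference vectors between spot vectors, keeps
#' those whose length matches one of the estimated reciprocal cell lengths
#' within `length_tol`, folds antiparallel vectors together, and clusters
#' the survivors by direction.  Each cluster is a candidate basis vector
#' (the cluster mean), with its population as a quality weight.
#'
#' @param spot_vectors Matrix or tibble of spot vectors (`gx, gy, gz`).
#' @param length_estimates Numeric vector of expected reciprocal lengths
#'   (1/A), e.g. from [estimate_basis_lengths()].
#' @param length_tol Fractional length tolerance (default 0.1).
#' @param cluster_angle Direction-clustering tolerance in degrees.
#' @param min_cluster Minimum cluster population to keep.
#' @return Tibble `gx, gy, gz, length, n, estimate` sorted by decreasing
#'   population; zero rows (with a message) when nothing matches.
#' @export
candidate_basis_vectors <- function(spot_vectors, length_estimates,
                                    length_tol = 0.1, cluster_angle = 6,
                                    min_cluster = 3) {
  stopifnot(length(length_estimates) >= 1, all(length_estimates > 0))
  D <- difference_vectors(spot_vectors,
                          max_length = max(length_estimates) * (1 + 2 * length_tol))
  est <- vapply(D$length, function(L) {
    rel <- abs(L - length_estimates) / length_estimates
    i <- which.min(rel)
    if (rel[i] <= length_tol) length_estimates[i] else NA_real_
  }, numeric(1))
  keep <- !is.na(est)
  if (!any(keep)) {
    message("no difference vectors match the length estimates within tolerance")
    return(tibble::tibble(gx = numeric(), gy = numeric(), gz = numeric(),
                          length = numeric(), n = integer(),
                          estimate = numeric()))
  }
  V <- as_g_matrix(D[keep, c("gx", "gy", "gz")])
  est <- est[keep]
  V <- fold_antiparallel(V)
  ulen <- sqrt(rowSums(V^2))
  Un <- V / ulen
  cos_tol <- cos(cluster_angle * pi / 180)
  assigned <- rep(FALSE, nrow(V))
  out <- list()
  ord <- order(ulen)  # deterministic seeding: shortest first
  for (i in ord) {
    if (assigned[i]) next
    sim <- abs(Un %*% Un[i, ]) >= cos_tol
    memb <- which(!assigned & sim & abs(ulen - ulen[i]) / ulen[i] <= length_tol)
    if (!length(memb)) next
    assigned[memb] <- TRUE
    # fold members onto the seed's hemisphere before averaging
    sgn <- sign(Un[memb, , drop = FALSE] %*% Un[i, ])
    sgn[sgn == 0] <- 1
    vbar <- colMeans(V[memb, , drop = FALSE] * as.numeric(sgn))
    out[[length(out) + 1]] <- tibble::tibble(
      gx = vbar[1], gy = vbar[2], gz = vbar[3],
      length = sqrt(sum(vbar^2)), n = length(memb),
      estimate = est[i])
  }
  res <- dplyr::bind_rows(out)
  res <- res[res$n >= min_cluster, ]
  dplyr::arrange(res, dplyr::desc(.data$n))
}

# Flip vectors so the largest-magnitude component is positive.
fold_antiparallel <- function(V) {
  lead <- max.col(abs(V), ties.method = "first")
  sgn <- sign(V[cbind(seq_len(nrow(V)), lead)])
  sgn[sgn == 0] <- 1
  V * sgn
}

#' Orthogonal-triplet search for the reciprocal basis
#'
#' Enumerates all triples of candidate vectors whose pairwise angles are
#' within `angle_tol` of 90 degrees ("orthogonal triplets").  Among valid
#' triplets the winner is the one indexing the largest fraction of the
#' spot vectors to near-integer Miller indices (tie-break: smallest total
#' length); all triplets compatible with the winner's axis directions are
#' then averaged per axis.  Axes are labelled by length — the two most
#' similar lengths become a* and b*, the remaining one c* — and the basis
#' is made right-handed (a* x b* . c* > 0).
#'
#' Consistency scoring matters because harmonic and diagonal combinations
#' (for instance \{b*, 2a*, c*\} or \{a*+b*, a*-b*, c*\}) are also mutually
#' orthogonal in a tetragonal lattice but index the spot set poorly.
#' Only right-angle lattices are searched; data from a cell with
#' non-90-degree angles will fail with an indexing error.
#'
#' @param candidates Tibble from [candidate_basis_vectors()].
#' @param spot_vectors Optional spot vectors used for consistency scoring
#'   (strongly recommended).
#' @param angle_tol Angular tolerance around 90 degrees (default 5).
#' @param residual_tol Miller-index residual for the scoring (default 0.2).
#' @param max_candidates Cap on candidates entering the combinatorial
#'   search (taken in population order).
#' @return A `microed_basis` with attributes `n_triplets` (averaged) and
#'   `score` (indexed fraction of the spot vectors, when supplied).
#' @export
orthogonal_triplets <- function(candidates, spot_vectors = NULL,
                                angle_tol = 5, residual_tol = 0.2,
                                max_candidates = 40) {
  if (nrow(candidates) < 3) {
    stop("need at least 3 candidate vectors", call. = FALSE)
  }
  cand <- utils::head(candidates, max_candidates)
  V <- as_g_matrix(cand[, c("gx", "gy", "gz")])
  len <- sqrt(rowSums(V^2))
  Un <- V / len
  C <- abs(Un %*% t(Un))          # |cos| of pairwise angles
  ok_pair <- C <= cos((90 - angle_tol) * pi / 180)
  trips <- list()
  nc <- nrow(V)
  for (i in 1:(nc - 2)) for (j in (i + 1):(nc - 1)) {
    if (!ok_pair[i, j]) next
    for (k in (j + 1):nc) {
      if (ok_pair[i, k] && ok_pair[j, k]) trips[[length(trips) + 1]] <- c(i, j, k)
    }
  }
  if (!length(trips)) {
    closest <- 90 - acos(min(C[upper.tri(C)])) * 180 / pi
    stop(sprintf(
      "indexing failed: no orthogonal triplet within %g deg (closest pair %.2f deg off 90)",
      angle_tol, closest), call. = FALSE)
  }
  # Cluster means carry a few percent of length error, which destroys the
  # indexed fraction at high Miller orders; polish each triplet by
  # bootstrap least squares before scoring so the score reflects the
  # triplet's directions, not its raw length noise.
  score_of <- function(tr) {
    B <- t(V[tr, , drop = FALSE])
    if (abs(det(B)) < 1e-12) return(c(-1, Inf))
    if (is.null(spot_vectors)) return(c(0, sum(len[tr])))
    B <- ls_polish(B, spot_vectors, residual_tol)
    frac <- fraction_indexed(B, spot_vectors, residual_tol)
    c(frac, sum(len[tr]))
  }
  sc <- vapply(trips, score_of, numeric(2))
  best <- which(sc[1, ] == max(sc[1, ]))
  best <- best[which.min(sc[2, best])]
  axes <- Un[trips[[best]], , drop = FALSE]
  # average all triplets whose three directions match the winner's
  cos_tol <- cos(angle_tol * pi / 180)
  members <- lapply(1:3, function(a) numeric(0))
  n_used <- 0L
  for (tr in trips) {
    m <- abs(Un[tr, , drop = FALSE] %*% t(axes))  # 3 x 3 |cos| to winner axes
    perm <- apply(m, 2, which.max)
    if (length(unique(perm)) != 3 ||
        any(m[cbind(perm, 1:3)] < cos_tol)) next
    lens_tr <- len[tr][perm]
    if (any(abs(lens_tr - len[trips[[best]]]) / len[trips[[best]]] > 0.1)) next
    n_used <- n_used + 1L
    for (a in 1:3) {
      v <- V[tr[perm[a]], ]
      if (sum(v * axes[a, ]) < 0) v <- -v
      members[[a]] <- rbind(members[[a]], v)
    }
  }
  axis_vecs <- t(vapply(members, function(m) colMeans(matrix(m, ncol = 3)),
                        numeric(3)))
  # Harmonic check: an axis candidate may be an integer multiple of the
  # true basis vector (difference vectors m*a are lattice vectors too).
  # Dividing a correct axis by an integer also never *decreases* the
  # indexed fraction (it makes a reciprocal superlattice), so a division
  # is accepted only on a substantial score jump; accidental halvings
  # that slip through are undone by the parity analysis below.
  Bm <- t(axis_vecs)
  if (!is.null(spot_vectors)) {
    Bm <- ls_polish(Bm, spot_vectors, residual_tol)
    margin <- 0.1
    for (a in 1:3) {
      sc_m <- vapply(1:3, function(m) {
        Bt <- Bm; Bt[, a] <- Bt[, a] / m
        fraction_indexed(ls_polish(Bt, spot_vectors, residual_tol),
                         spot_vectors, residual_tol)
      }, numeric(1))
      m_best <- which.max(sc_m)
      if (m_best > 1 && sc_m[m_best] > sc_m[1] + margin) {
        Bm[, a] <- Bm[, a] / m_best
        Bm <- ls_polish(Bm, spot_vectors, residual_tol)
      }
    }
    Bm <- fix_sublattice(Bm, spot_vectors, residual_tol)
  }
  basis <- reciprocal_basis(label_axes(Bm))
  attr(basis, "n_triplets") <- n_used
  attr(basis, "score") <- if (is.null(spot_vectors)) NA_real_ else max(sc[1, ])
  basis
}

# Conventional axis labelling: the two closest lengths become a*, b*; the
# remaining axis is c*; handedness fixed by a* x b* . c* > 0 (flip c*).
label_axes <- function(Bm) {
  alen <- sqrt(colSums(Bm^2))
  gaps <- c(abs(alen[1] - alen[2]), abs(alen[1] - alen[3]),
            abs(alen[2] - alen[3]))
  pair <- list(c(1, 2), c(1, 3), c(2, 3))[[which.min(gaps)]]
  Bm <- Bm[, c(pair, setdiff(1:3, pair)), drop = FALSE]
  if (det(Bm) < 0) Bm[, 3] <- -Bm[, 3]
  Bm
}

# Superlattice (centering) correction: a basis of short difference vectors
# can generate a reciprocal superlattice of the true lattice, e.g.
# {(a*+b*)/2, (a*-b*)/2} — every spot still indexes to integers, but the
# indexed Miller indices then obey a parity rule (here: h + k always
# even).  Detect such rules on the indexed spots and apply the
# corresponding integer basis transformation until none holds.  A small
# fraction of indexed outliers (noise maxima) carries random parity, so
# the rule fires on a high fraction rather than on all spots: a true
# lattice sits near 50% even, a superlattice description near 100%.
fix_sublattice <- function(Bm, spot_vectors, residual_tol,
                           max_pass = 3, parity_frac = 0.95) {
  G <- as_g_matrix(spot_vectors)
  transforms <- list(
    h      = list(even = function(H) H[, 1],
                  T = diag(c(2, 1, 1))),
    k      = list(even = function(H) H[, 2],
                  T = diag(c(1, 2, 1))),
    l      = list(even = function(H) H[, 3],
                  T = diag(c(1, 1, 2))),
    hk     = list(even = function(H) H[, 1] + H[, 2],
                  T = cbind(c(1, 1, 0), c(-1, 1, 0), c(0, 0, 1))),
    hl     = list(even = function(H) H[, 1] + H[, 3],
                  T = cbind(c(1, 0, 1), c(0, 1, 0), c(-1, 0, 1))),
    kl     = list(even = function(H) H[, 2] + H[, 3],
                  T = cbind(c(1, 0, 0), c(0, 1, 1), c(0, -1, 1))),
    hkl    = list(even = function(H) H[, 1] + H[, 2] + H[, 3],
                  T = cbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))))
  for (pass in seq_len(max_pass)) {
    fr <- t(solve(Bm) %*% t(G))
    res <- apply(abs(fr - round(fr)), 1, max)
    H <- round(fr[res <= residual_tol, , drop = FALSE])
    H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
    if (nrow(H) < 10) return(Bm)
    hit <- FALSE
    for (tr in transforms) {
      if (mean(tr$even(H) %% 2 == 0) >= parity_frac) {
        Bnew <- ls_polish(Bm %*% tr$T, G, residual_tol)
        # the transformed basis must keep indexing the (non-outlier) spots
        if (fraction_indexed(Bnew, G, residual_tol) >=
            fraction_indexed(Bm, G, residual_tol) - (1 - parity_frac)) {
          Bm <- Bnew; hit <- TRUE; break
        }
      }
    }
    if (!hit) return(Bm)
  }
  Bm
}

# Bootstrap least-squares basis polish: index with a loose residual cut,
# re-solve the basis from the integer assignments, tighten, repeat.
ls_polish <- function(Bm, spot_vectors, residual_tol,
                      tols = c(0.35, 0.25, residual_tol)) {
  G <- as_g_matrix(spot_vectors)
  for (tol in tols) {
    fr <- t(solve(Bm) %*% t(G))
    res <- apply(abs(fr - round(fr)), 1, max)
    sel <- res <= tol
    if (sum(sel) < 6) next
    H <- round(fr[sel, , drop = FALSE])
    XtX <- crossprod(H)
    if (abs(det(XtX)) < 1e-9) next
    Bnew <- t(solve(XtX, crossprod(H, G[sel, , drop = FALSE])))
    if (abs(det(Bnew)) > 1e-12) Bm <- Bnew
  }
  Bm
}

fraction_indexed <- function(Bmat, spot_vectors, residual_tol) {
  G <- as_g_matrix(spot_vectors)
  frac <- t(solve(Bmat) %*% t(G))
  res <- apply(abs(frac - round(frac)), 1, max)
  mean(res <= residual_tol)
}

#' Refine a reciprocal basis against the spot set
#'
#' Two stages.  (1) Parallel-multiples averaging: difference vectors of
#' the original spots that are parallel to an axis (within `angle_tol`)
#' and whose length is an integer multiple `m` of the axis length (within
#' `multiple_tol`) are rescaled by `1/m` and averaged with the axis.
#' (2) Optional least-squares polish: spots indexing within
#' `residual_tol` are assigned integer Miller indices and the basis is
#' re-solved by linear least squares.  Each stage is accepted only if the
#' median fractional Miller residual of the spot set does not increase,
#' so refinement never degrades the solution.
#'
#' @param basis A `microed_basis`.
#' @param spot_vectors Spot vectors (matrix or tibble `gx, gy, gz`).
#' @param angle_tol Parallelism tolerance in degrees.
#' @param multiple_tol Fractional tolerance on the integer-multiple match.
#' @param max_multiple Largest multiple considered.
#' @param residual_tol Residual cut for the least-squares stage.
#' @param lsq Run the least-squares polish (default `TRUE`).
#' @param n_iter Iterations of the full cycle.
#' @return A refined `microed_basis`.
#' @export
refine_basis <- function(basis, spot_vectors, angle_tol = 3,
                         multiple_tol = 0.07, max_multiple = 6,
                         residual_tol = 0.2, lsq = TRUE, n_iter = 2) {
  G <- as_g_matrix(spot_vectors)
  D <- difference_vectors(G)
  Dm <- as_g_matrix(D[, c("gx", "gy", "gz")])
  dlen <- D$length
  metric <- function(B) {
    fr <- t(solve(B) %*% t(G))
    res <- apply(abs(fr - round(fr)), 1, max)
    stats::median(pmin(res, 0.5))
  }
  B <- basis_matrix(basis)
  cur <- metric(B)
  cos_tol <- cos(angle_tol * pi / 180)
  for (it in seq_len(n_iter)) {
    Bnew <- B
    for (a in 1:3) {
      axis <- B[, a]; alen <- sqrt(sum(axis^2))
      cosang <- abs(Dm %*% axis) / (dlen * alen)
      m <- round(dlen / alen)
      par_ok <- cosang >= cos_tol & m >= 1 & m <= max_multiple &
        abs(dlen / m - alen) / alen <= multiple_tol
      if (!any(par_ok)) next
      W <- Dm[par_ok, , drop = FALSE] / m[par_ok]
      sgn <- sign(W %*% axis); sgn[sgn == 0] <- 1
      Bnew[, a] <- colMeans(W * as.numeric(sgn))
    }
    if (metric(Bnew) <= cur) { B <- Bnew; cur <- metric(B) }
    if (lsq) {
      fr <- t(solve(B) %*% t(G))
      res <- apply(abs(fr - round(fr)), 1, max)
      sel <- res <= residual_tol
      if (sum(sel) >= 6) {
        H <- round(fr[sel, , drop = FALSE])
        if (abs(det(crossprod(H))) > 1e-9) {
          Bls <- t(solve(crossprod(H), crossprod(H, G[sel, , drop = FALSE])))
          if (metric(Bls) <= cur) { B <- Bls; cur <- metric(B) }
        }
      }
    }
  }
  out <- reciprocal_basis(B)
  attr(out, "median_residual") <- cur
  out
}

#' Assign Miller indices to spot vectors
#'
#' Solves each spot vector against the basis for fractional Miller
#' indices; spots whose fractional indices are all within `residual_tol`
#' of integers are assigned the rounded `(h, k, l)`.
#'
#' @param basis A `microed_basis`.
#' @param spot_vectors Matrix or tibble of spot vectors (`gx, gy, gz`).
#' @param residual_tol Maximum |fractional - integer| residual.
#' @return Tibble `h, k, l, fh, fk, fl, residual, indexed` (one row per
#'   spot; `h, k, l` are `NA` for unindexed spots), with attribute
#'   `fraction_indexed`.
#' @export
index_spots <- function(basis, spot_vectors, residual_tol = 0.2) {
  G <- as_g_matrix(spot_vectors)
  B <- basis_matrix(basis)
  fr <- t(solve(B) %*% t(G))
  res <- apply(abs(fr - round(fr)), 1, max)
  ok <- res <= residual_tol
  out <- tibble::tibble(
    h = ifelse(ok, as.integer(round(fr[, 1])), NA_integer_),
    k = ifelse(ok, as.integer(round(fr[, 2])), NA_integer_),
    l = ifelse(ok, as.integer(round(fr[, 3])), NA_integer_),
    fh = fr[, 1], fk = fr[, 2], fl = fr[, 3],
    residual = res, indexed = ok)
  attr(out, "fraction_indexed") <- mean(ok)
  out
}

#' Index a simulated or measured tilt series end to end
#'
#' Full autoindexing chain on a tilt series: pick spots on a set of
#' frames, map them to crystal-fixed reciprocal vectors, estimate the
#' reciprocal cell lengths from difference-vector statistics (unless
#' supplied), build candidate basis vectors, search orthogonal triplets,
#' and refine.  Deterministic given the spot list.
#'
#' When the consistency score (fraction of spots indexing to near-integer
#' Miller indices) of the first attempt falls below `min_score`, the spot
#' budget is escalated — more frames, more spots per frame — and indexing
#' is repeated; this mirrors the manual practice of choosing additional
#' spots from additional images when a first indexing attempt is poor,
#' and keeps the default budget at the usual 100-350 spots.
#'
#' @param series A `microed_series` (frames are rendered on demand).
#' @param frames Frame indices to pick spots from; default: 13 frames
#'   evenly spaced across the series (escalation may add more).
#' @param max_spots_per_frame Spot budget per frame (total target:
#'   100-350 spots across the chosen frames).
#' @param length_estimates Optional reciprocal-length estimates (1/A).
#' @param threshold Spot-picking threshold (sigma over background).
#' @param length_tol,angle_tol,residual_tol Tolerances passed through to
#'   the respective stages.
#' @param min_score Indexed fraction below which the spot budget is
#'   escalated (default 0.9).
#' @return List: `basis` (refined `microed_basis`), `cell` (direct
#'   [unit_cell()]), `spots` (picked spots with frame/tilt), `indexed`
#'   (per-spot index assignments), `fraction_indexed`, `length_estimates`,
#'   `attempts`.
#' @export
index_tilt_series <- function(series, frames = NULL,
                              max_spots_per_frame = 25,
                              length_estimates = NULL,
                              threshold = 5, length_tol = 0.1,
                              angle_tol = 5, residual_tol = 0.2,
                              min_score = 0.9) {
  stopifnot(inherits(series, "microed_series"))
  n <- nrow(series$meta)
  budgets <- list(
    list(frames = frames %||% unique(round(seq(1, n, length.out = min(13, n)))),
         spots = max_spots_per_frame),
    list(frames = unique(round(seq(1, n, length.out = min(21, n)))),
         spots = max(40, max_spots_per_frame)),
    list(frames = unique(round(seq(1, n, length.out = min(31, n)))),
         spots = max(60, max_spots_per_frame)))
  if (!is.null(frames)) budgets <- budgets[1]
  res <- NULL
  last_err <- NULL
  for (att in seq_along(budgets)) {
    b <- budgets[[att]]
    res <- tryCatch(
      index_spot_set(series, b$frames, b$spots, length_estimates,
                     threshold, length_tol, angle_tol, residual_tol),
      error = function(e) e)
    if (!inherits(res, "error") && res$fraction_indexed >= min_score) {
      res$attempts <- att
      return(res)
    }
    if (inherits(res, "error")) last_err <- res
  }
  if (inherits(res, "error")) {
    stop("indexing failed after escalation: ", conditionMessage(last_err %||% res),
         call. = FALSE)
  }
  res$attempts <- length(budgets)
  res
}

index_spot_set <- function(series, frames, max_spots_per_frame,
                           length_estimates, threshold, length_tol,
                           angle_tol, residual_tol) {
  spot_list <- list()
  for (f in frames) {
    img <- get_frame(series, f)
    sp <- pick_spots(img, geom = series$geom, threshold = threshold,
                     max_spots = max_spots_per_frame)
    if (nrow(sp)) {
      sp$frame <- f
      sp$tilt <- series$meta$tilt[f]
      spot_list[[length(spot_list) + 1]] <- sp
    }
  }
  spots <- dplyr::bind_rows(spot_list)
  if (nrow(spots) < 20) stop("too few spots picked for indexing", call. = FALSE)
  gl <- lapply(split(spots, spots$frame), function(df) {
    spot_to_reciprocal(df[, c("x", "y")], df$tilt[1], series$geom)
  })
  G <- as.matrix(dplyr::bind_rows(gl))
  if (is.null(length_estimates)) {
    D <- difference_vectors(G, max_length = 0.05)
    length_estimates <- estimate_basis_lengths(D)
  }
  cand <- candidate_basis_vectors(G, length_estimates, length_tol = length_tol)
  basis <- orthogonal_triplets(cand, spot_vectors = G, angle_tol = angle_tol,
                               residual_tol = residual_tol)
  basis <- refine_basis(basis, G, residual_tol = residual_tol)
  idx <- index_spots(basis, G, residual_tol = residual_tol)
  list(basis = basis,
       cell = cell_from_basis(basis, space_group = series$cell$space_group),
       spots = spots, indexed = idx,
       fraction_indexed = attr(idx, "fraction_indexed"),
       length_estimates = length_estimates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
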