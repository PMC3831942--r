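#' Crystallographic unit cell
#'
#' @param a,b,c Direct-cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#' @param space_group Space-group label, e.g. `"P43212"`.  Only used for
#'   systematic-absence rules and file headers; geometry depends on the
#'   cell parameters alone.
#' @return An object of class `microed_cell`.
#' @examples
#' unit_cell(77, 77, 37, space_group = "P43212")
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      space_group = "P1") {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive", call. = FALSE)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         space_group = space_group),
    class = "microed_cell")
  if (cell_volume(cell) <= 0) stop("cell volume must be positive", call. = FALSE)
  cell
}

#' Reference tetragonal lysozyme cell
#'
#' The tetragonal hen egg-white lysozyme cell used throughout the package's
#' simulations: a = b = 77 A, c = 37 A, alpha = beta = gamma = 90 deg,
#' space group P4(3)2(1)2.
#'
#' @return A [unit_cell()].
#' @examples
#' reference_cell()
#' @export
reference_cell <- function() {
  unit_cell(77, 77, 37, 90, 90, 90, space_group = "P43212")
}

#' @export
print.microed_cell <- function(x, ...) {
  cat(sprintf("<microed_cell> a=%.4g b=%.4g c=%.4g A  alpha=%g beta=%g gamma=%g deg  %s\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$space_group))
  invisible(x)
}

#' Unit-cell volume
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

# Direct-basis matrix, rows a, b, c (standard orthogonalization:
# a along x, b in the xy plane).
direct_basis_matrix <- function(cell) {
  al <- cell$alpha * pi / 180; be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  v <- cell_volume(cell)
  cx <- cell$c * cos(be)
  cy <- cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- v / (cell$a * cell$b * sin(ga))
  rbind(c(cell$a, 0, 0),
        c(cell$b * cos(ga), cell$b * sin(ga), 0),
        c(cx, cy, cz))
}

#' Reciprocal basis of a unit cell
#'
#' Returns the reciprocal basis vectors a*, b*, c* (columns of a 3x3
#' matrix, in 1/A, crystallographic convention `a . a* = 1`) for a cell in
#' a standard orientation.  A Miller index `v = (h, k, l)` maps to the
#' reciprocal vector `r = h a* + k b* + l c* = B %*% v`.
#'
#' @param cell A [unit_cell()].
#' @return A `microed_basis` object (see [reciprocal_basis()]).
#' @export
cell_to_basis <- function(cell) {
  A <- direct_basis_matrix(cell)
  reciprocal_basis(solve(A))  # columns a*, b*, c*: A %*% B = I
}

#' Reciprocal-basis object
#'
#' Wraps a 3x3 matrix whose columns are the reciprocal basis vectors
#' a*, b*, c* (1/A) in the crystal-fixed zero-tilt frame.  The columns must
#' be linearly independent.
#'
#' @param mat 3x3 numeric matrix, columns a*, b*, c*.
#' @return An object of class `microed_basis`.
#' @export
reciprocal_basis <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(identical(dim(mat), c(3L, 3L)))
  if (abs(det(mat)) < 1e-12) {
    stop("reciprocal basis vectors must be linearly independent", call. = FALSE)
  }
  structure(list(mat = mat), class = "microed_basis")
}

#' @export
print.microed_basis <- function(x, ...) {
  len <- sqrt(colSums(x$mat^2))
  cat("<microed_basis> |a*|, |b*|, |c*| =",
      paste(sprintf("%.6g", len), collapse = ", "), "1/A\n")
  cell <- cell_from_basis(x)
  cat(sprintf("  direct cell: %.4g %.4g %.4g A, %.3g %.3g %.3g deg\n",
              cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  invisible(x)
}

basis_matrix <- function(basis) {
  if (inherits(basis, "microed_basis")) basis$mat else as.matrix(basis)
}

#' Direct cell from a reciprocal basis
#'
#' Inverts a reciprocal basis to the direct-cell parameters
#' `(a, b, c, alpha, beta, gamma)`.  Axis labels follow the basis columns;
#' use [orthogonal_triplets()] to obtain a conventionally labelled basis
#' (the two near-equal axes as a, b).
#'
#' @param basis A `microed_basis` or 3x3 matrix (columns a*, b*, c*).
#' @param space_group Label to attach to the resulting cell.
#' @return A [unit_cell()].
#' @export
cell_from_basis <- function(basis, space_group = "P1") {
  B <- basis_matrix(basis)
  A <- solve(B)  # rows a, b, c since A %*% B = I
  len <- sqrt(rowSums(A^2))
  ang <- function(u, v) {
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  unit_cell(len[1], len[2], len[3],
            alpha = ang(A[2, ], A[3, ]),
            beta  = ang(A[1, ], A[3, ]),
            gamma = ang(A[1, ], A[2, ]),
            space_group = space_group)
}

#' Resolution of Miller indices in a cell
#'
#' @param cell A [unit_cell()].
#' @param hkl Length-3 vector or n x 3 matrix / data frame with columns
#'   `h, k, l`.
#' @return d-spacings in Angstrom (Inf for (0,0,0)).
#' @export
d_spacing <- function(cell, hkl) {
  H <- as_hkl_matrix(hkl)
  B <- basis_matrix(cell_to_basis(cell))
  g <- H %*% t(B)
  1 / sqrt(rowSums(g^2))
}

as_hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "double"
  hkl
}
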