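# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Reference-cell tilt series at a fixed random orientation; truth table
# only (frames rendered on demand by the tests that need them).
test_series <- function() {
  if (is.null(.fixtures$series)) {
    .fixtures$series <- simulate_tilt_series(
      orientation = random_orientation(107), seed = 3, render = FALSE)
  }
  .fixtures$series
}

# True reciprocal basis of a series in the crystal-fixed frame.
true_basis <- function(series) {
  series$orientation %*% cell_to_basis(series$cell)$mat
}

# Lattice spot vectors (no noise) for indexing tests: n low-resolution
# reflections of the reference cell at a fixed orientation.  The compact
# region guarantees plenty of lattice-neighbour pairs, so difference
# vectors include the basis vectors themselves.
lattice_vectors <- function(n = 300, seed = 5, orientation = c(20, -35, 50)) {
  set.seed(seed)
  cell <- reference_cell()
  refl <- enumerate_hkl(cell, 6, 80)
  refl <- refl[sample(nrow(refl), min(n, nrow(refl))), ]
  B <- orientation_matrix_test(orientation) %*% cell_to_basis(cell)$mat
  list(G = as.matrix(refl[, c("h", "k", "l")]) %*% t(B), B = B, hkl = refl)
}

# Independent extrinsic Rz Ry Rx rotation (kept separate from the package
# implementation on purpose).
orientation_matrix_test <- function(deg) {
  a <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Small synthetic image with a 2D Gaussian of total volume `total`.
gaussian_image <- function(nx = 64, ny = 64, x0 = 31.5, y0 = 31.5,
                           total = 1e4, sigma = 2, background = 0) {
  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  img <- background +
    (total / (2 * pi * sigma^2)) *
    outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
          exp(-(xs - x0)^2 / (2 * sigma^2)))
  img
}

# Plateau-then-linear dose response, written independently of the package.
dose_factor_oracle <- function(D, Dc, rate) {
  pmax(0, 1 - rate * pmax(0, D - Dc))
}

# The 16 Laue 4/mmm operator matrices written out explicitly — the
# brute-force oracle for orbit tests (independent of the package's
# group-closure construction).
laue_ops_oracle <- function() {
  ops8 <- list(
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),     # identity
    rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)),    # 4+ about c
    rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1)),   # 2 about c
    rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)),    # 4- about c
    rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1)),   # 2 about a
    rbind(c(-1, 0, 0), c(0, 1, 0), c(0, 0, -1)),   # 2 about b
    rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1)),    # 2 about [110]
    rbind(c(0, -1, 0), c(-1, 0, 0), c(0, 0, -1)))  # 2 about [1-10]
  c(ops8, lapply(ops8, function(m) -m))
}

orbit_oracle <- function(hkl) {
  orb <- unique(t(vapply(laue_ops_oracle(), function(m) as.numeric(m %*% hkl),
                         numeric(3))))
  orb[order(orb[, 1], orb[, 2], orb[, 3]), , drop = FALSE]
}
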