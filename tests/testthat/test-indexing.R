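test_that("spot picking: blank frames, injected spots, spot budget", {
  # background-only frame: nothing above threshold
  blank <- matrix(20, 128, 128)
  expect_equal(nrow(pick_spots(blank)), 0)

  # k injected Gaussians well above background are all found within 1 px
  set.seed(31)
  n_inj <- 12
  pos <- cbind(runif(n_inj, 20, 235), runif(n_inj, 20, 235))
  # keep injected spots well separated and away from the centre exclusion
  pos <- pos[sqrt((pos[, 1] - 127.5)^2 + (pos[, 2] - 127.5)^2) > 20, ]
  img <- matrix(20, 256, 256)
  for (i in seq_len(nrow(pos))) {
    img <- img + gaussian_image(256, 256, pos[i, 1], pos[i, 2],
                                total = 5e3, sigma = 1.5)
  }
  set.seed(32)
  img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  found <- pick_spots(img, threshold = 6)
  expect_equal(nrow(found), nrow(pos))
  dmin_px <- apply(pos, 1, function(p) {
    min(sqrt((found$x - p[1])^2 + (found$y - p[2])^2))
  })
  expect_lt(max(dmin_px), 1)

  # default budget on a simulated series: 100-350 spots in total
  ser <- test_series()
  frames <- unique(round(seq(1, 91, length.out = 13)))
  ser_r <- render_frames(ser, frames = frames)
  n_tot <- sum(vapply(frames, function(f) {
    nrow(pick_spots(ser_r$frames[[as.character(f)]], geom = ser$geom,
                    max_spots = 25))
  }, numeric(1)))
  expect_gte(n_tot, 100)
  expect_lte(n_tot, 350)
})

test_that("difference vectors of a perfect lattice contain the basis", {
  lat <- lattice_vectors(n = 150)
  cand <- candidate_basis_vectors(lat$G, sqrt(colSums(lat$B^2)),
                                  length_tol = 0.02, cluster_angle = 1)
  expect_gte(nrow(cand), 3)
  # each true basis vector appears as a cluster mean (up to sign), exactly
  for (a in 1:3) {
    v <- lat$B[, a]
    errs <- apply(as.matrix(cand[, c("gx", "gy", "gz")]), 1, function(w) {
      min(sqrt(sum((w - v)^2)), sqrt(sum((w + v)^2)))
    })
    expect_lt(min(errs) / sqrt(sum(v^2)), 1e-9)
  }
})

test_that("noisy difference clusters recover the true lengths", {
  lat <- lattice_vectors(n = 200, seed = 8)
  sigma <- 5e-5
  set.seed(41)
  Gn <- lat$G + matrix(rnorm(length(lat$G), sd = sigma), ncol = 3)
  cand <- candidate_basis_vectors(Gn, sqrt(colSums(lat$B^2)),
                                  length_tol = 0.08)
  Un <- as.matrix(cand[, c("gx", "gy", "gz")]) / cand$length
  for (a in c(1, 3)) {   # one short and one long axis
    v <- lat$B[, a]; true_len <- sqrt(sum(v^2))
    # the cluster aligned with the true axis at a compatible length
    ali <- abs(Un %*% (v / true_len))
    sel <- which(abs(cand$length - true_len) / true_len < 0.08 & ali > 0.999)
    expect_gt(length(sel), 0)
    best <- sel[which.max(cand$n[sel])]
    # cluster mean within a few standard errors of the truth
    tol <- 4 * sigma * sqrt(2) / sqrt(cand$n[best])
    expect_lt(abs(cand$length[best] - true_len), tol + 2e-6)
  }
})

test_that("orthogonal triplet search: fixed point and axis labelling", {
  lat <- lattice_vectors(n = 150)
  exact <- tibble::tibble(gx = lat$B[1, ], gy = lat$B[2, ], gz = lat$B[3, ],
                          length = sqrt(colSums(lat$B^2)),
                          n = c(10L, 10L, 10L),
                          estimate = sqrt(colSums(lat$B^2)))
  bas <- orthogonal_triplets(exact, spot_vectors = lat$G)
  # an exactly orthogonal triplet is returned unchanged up to
  # labelling/sign; the recovered cell is exact
  cl <- cell_from_basis(bas)
  expect_equal(c(cl$a, cl$b, cl$c), c(77, 77, 37), tolerance = 1e-6)
  expect_equal(c(cl$alpha, cl$beta, cl$gamma), c(90, 90, 90),
               tolerance = 1e-6)
  # basis is right-handed
  expect_gt(det(bas$mat), 0)
  expect_error(orthogonal_triplets(exact[1:2, ]), "at least 3")
})

test_that("refinement recovers from a perturbed axis and never degrades", {
  lat <- lattice_vectors(n = 250, seed = 12)
  Bp <- lat$B
  Bp[, 1] <- Bp[, 1] * 1.02   # +2% error in |a*|
  ref <- refine_basis(reciprocal_basis(Bp), lat$G)
  len_true <- sqrt(sum(lat$B[, 1]^2))
  expect_lt(abs(sqrt(sum(ref$mat[, 1]^2)) - len_true) / len_true, 0.001)

  # median fractional residual never increases through refinement
  set.seed(43)
  Gn <- lat$G + matrix(rnorm(length(lat$G), sd = 4e-5), ncol = 3)
  med_res <- function(B) {
    fr <- t(solve(B) %*% t(Gn))
    median(apply(abs(fr - round(fr)), 1, max))
  }
  ref_n <- refine_basis(reciprocal_basis(Bp), Gn)
  expect_lte(med_res(ref_n$mat), med_res(Bp))

  # perfect input is a fixed point (up to numerical noise)
  ref0 <- refine_basis(reciprocal_basis(lat$B), lat$G)
  expect_equal(ref0$mat, lat$B, tolerance = 1e-9)
})

test_that("index assignment: exact lattice, noise and random spots", {
  lat <- lattice_vectors(n = 200, seed = 14)
  idx <- index_spots(reciprocal_basis(lat$B), lat$G)
  expect_equal(mean(idx$indexed), 1)
  expect_lt(max(idx$residual), 1e-6)
  expect_equal(cbind(idx$h, idx$k, idx$l), unname(as.matrix(lat$hkl[, 1:3])))

  # noise at the sub-pixel scale still indexes nearly everything
  set.seed(44)
  px <- 1.248e-3  # reciprocal A per pixel at the binned geometry
  Gn <- lat$G + matrix(rnorm(length(lat$G), sd = 0.3 * px), ncol = 3)
  idx_n <- index_spots(reciprocal_basis(lat$B), Gn)
  expect_gte(mean(idx_n$indexed), 0.95)

  # uniformly random vectors index at the geometric-probability rate
  # (volume fraction of index space within the residual tolerance)
  set.seed(45)
  n_rand <- 4000
  Gr <- matrix(runif(3 * n_rand, -0.3, 0.3), ncol = 3)
  idx_r <- index_spots(reciprocal_basis(lat$B), Gr, residual_tol = 0.2)
  # independent Monte-Carlo oracle on uniform fractional indices
  fr <- matrix(runif(3 * 200000), ncol = 3)
  p_oracle <- mean(apply(abs(fr - round(fr)), 1, max) <= 0.2)
  p_se <- sqrt(p_oracle * (1 - p_oracle) / n_rand)
  expect_lt(abs(mean(idx_r$indexed) - p_oracle), 4 * p_se)

  expect_error(index_spots(reciprocal_basis(matrix(c(1, 0, 0, 2, 0, 0, 0, 0, 1),
                                                   3, 3)), lat$G),
               "independent")
})

test_that("indexing is deterministic and invariant to axis relabelling", {
  lat <- lattice_vectors(n = 180, seed = 16)
  set.seed(46)
  Gn <- lat$G + matrix(rnorm(length(lat$G), sd = 3e-5), ncol = 3)
  est <- sqrt(colSums(lat$B^2))
  cand <- candidate_basis_vectors(Gn, est)
  b1 <- orthogonal_triplets(cand, spot_vectors = Gn)
  b2 <- orthogonal_triplets(cand, spot_vectors = Gn)
  expect_identical(b1$mat, b2$mat)   # no internal randomness

  # swapping a* and b* or inverting an axis reports the same direct cell
  perms <- list(lat$B[, c(2, 1, 3)] %*% diag(c(1, 1, -1)),
                lat$B %*% diag(c(-1, 1, 1)),
                lat$B[, c(2, 1, 3)])
  cells <- lapply(perms, function(B) {
    cl <- cell_from_basis(B)
    round(sort(c(cl$a, cl$b, cl$c)), 9)
  })
  expect_true(all(vapply(cells, identical, logical(1), cells[[1]])))
})

test_that("full autoindexing recovers the cell across random orientations", {
  # end-to-end parameter recovery on simulated series at default noise
  for (s in 1:5) {
    ser <- simulate_tilt_series(orientation = random_orientation(200 + s),
                                seed = s, render = FALSE)
    res <- index_tilt_series(ser)
    cl <- res$cell
    expect_lt(abs(cl$a - 77) / 77, 0.01)
    expect_lt(abs(cl$b - 77) / 77, 0.01)
    expect_lt(abs(cl$c - 37) / 37, 0.01)
    expect_lt(max(abs(c(cl$alpha, cl$beta, cl$gamma) - 90)), 1)
    expect_gte(res$fraction_indexed, 0.9)
  }
})
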