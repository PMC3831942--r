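test_that("frame normal: cross-product identities and degeneracy", {
  B <- cell_to_basis(reference_cell())$mat
  bas <- reciprocal_basis(B)
  n <- frame_normal(c(1, 0, 0), c(0, 1, 0), bas)
  # cross product of a* and b* is parallel to c* in an orthogonal cell
  cs <- B[, 3] / sqrt(sum(B[, 3]^2))
  expect_equal(abs(sum(n / sqrt(sum(n^2)) * cs)), 1, tolerance = 1e-12)
  # orthogonal to both references, exactly
  set.seed(51)
  for (i in 1:10) {
    h1 <- sample(-5:5, 3, TRUE); h2 <- sample(-5:5, 3, TRUE)
    if (all(h1 == 0) || all(h2 == 0) ||
        max(abs(h1 * sum(h2^2) - h2 * sum(h1 * h2))) == 0) next
    n <- frame_normal(h1, h2, bas)
    expect_equal(sum(n * (B %*% h1)), 0, tolerance = 1e-15)
    expect_equal(sum(n * (B %*% h2)), 0, tolerance = 1e-15)
  }
  expect_error(frame_normal(c(1, 0, 0), c(2, 0, 0), bas), "collinear")
})

test_that("zone normal from reference spots matches the stage rotation", {
  ser <- test_series()
  B <- reciprocal_basis(true_basis(ser))
  f <- which(ser$meta$tilt == 20)
  tr <- ser$truth[ser$truth$frame == f, ]
  tr <- tr[order(-tr$I_spot), ]
  # second reference: strongest spot subtending > 30 deg with the first
  g1 <- as.numeric(B$mat %*% unlist(tr[1, c("h", "k", "l")]))
  j <- which(vapply(seq_len(nrow(tr)), function(i) {
    gi <- as.numeric(B$mat %*% unlist(tr[i, c("h", "k", "l")]))
    abs(sum(g1 * gi)) / sqrt(sum(g1^2) * sum(gi^2)) < cos(30 * pi / 180)
  }, logical(1)))[1]
  n <- frame_normal(unlist(tr[1, c("h", "k", "l")]),
                    unlist(tr[j, c("h", "k", "l")]), B)
  # the zone normal must align with the beam axis rotated into the
  # crystal-fixed frame at this tilt
  R <- microed:::tilt_rotation(20, ser$geom$tilt_axis)
  n_expected <- as.numeric(t(R) %*% c(0, 0, 1))
  ang <- acos(min(1, abs(sum(n * n_expected)) / sqrt(sum(n^2)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("prediction: zero layer and exact brute-force equality", {
  B <- cell_to_basis(reference_cell())$mat
  bas <- reciprocal_basis(B)
  # n parallel to c*: the zero layer (h, k, 0) exactly, at a small threshold
  pred <- predict_reflections(B[, 3], bas, dmin = 5, zone_threshold = 1e-9)
  expect_true(all(pred$l == 0))
  hmax <- ceiling(77 / 5)
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax)
  g <- g[!(g$h == 0 & g$k == 0), ]
  g <- g[77 / sqrt(g$h^2 + g$k^2) >= 5, ]
  expect_equal(nrow(pred), nrow(g))

  # 50 random frames: prediction equals an independent triple loop
  set.seed(52)
  U <- orientation_matrix_test(c(12, -40, 77))
  Bu <- U %*% B
  # dmin deliberately incommensurate with the cell so no reflection sits
  # exactly on the resolution boundary
  hmax <- ceiling(77 / 3.47); lmax <- ceiling(37 / 3.47)
  all_hkl <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -lmax:lmax)
  all_hkl <- all_hkl[!(all_hkl$h == 0 & all_hkl$k == 0 & all_hkl$l == 0), ]
  d_all <- 1 / sqrt((all_hkl$h^2 + all_hkl$k^2) / 77^2 + all_hkl$l^2 / 37^2)
  Gm <- as.matrix(all_hkl) %*% t(Bu)
  for (i in 1:50) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    thr <- runif(1, 0.005, 0.05)
    keep <- d_all >= 3.47 & d_all <= 19.97 &
      abs(Gm %*% n) / sqrt(rowSums(Gm^2)) <= thr
    oracle <- all_hkl[keep, ]
    pred <- predict_reflections(n, reciprocal_basis(Bu), dmin = 3.47,
                                dmax = 19.97, zone_threshold = thr)
    expect_equal(nrow(pred), nrow(oracle))
    expect_setequal(paste(pred$h, pred$k, pred$l),
                    paste(oracle$h, oracle$k, oracle$l))
  }
  expect_error(predict_reflections(c(0, 0, 1), bas, dmin = 3,
                                   zone_threshold = -1), "positive")
})

test_that("prediction recalls the rendered ground truth", {
  ser <- test_series()
  B <- reciprocal_basis(true_basis(ser))
  rho <- ser$params$rocking_half_width
  recalls <- vapply(c(15, 46, 77), function(f) {
    tilt <- ser$meta$tilt[f]
    R <- microed:::tilt_rotation(tilt, ser$geom$tilt_axis)
    n <- as.numeric(t(R) %*% c(0, 0, 1))
    pred <- predict_reflections(n, B, dmin = 2.9, dmax = 20,
                                rocking_half_width = rho)
    tr <- ser$truth[ser$truth$frame == f, ]
    mean(paste(tr$h, tr$k, tr$l) %in% paste(pred$h, pred$k, pred$l))
  }, numeric(1))
  expect_gte(min(recalls), 0.99)
})

test_that("square/circle mask integration: cancellation and linearity", {
  # uniform image integrates to exactly zero
  img <- matrix(7.3, 41, 41)
  expect_equal(integrate_spot(img, c(20, 20)), 0)
  # a linear ramp cancels by mask point symmetry
  ramp <- outer(seq_len(41), seq_len(41), function(i, j) 2.5 * i - 1.2 * j)
  expect_equal(integrate_spot(ramp, c(20, 20)), 0, tolerance = 1e-9)
  # adding a constant changes nothing
  g1 <- gaussian_image(41, 41, 20, 20, total = 5e3, sigma = 2)
  expect_equal(integrate_spot(g1 + 123.4, c(20, 20)),
               integrate_spot(g1, c(20, 20)), tolerance = 1e-9)
  # linearity
  g2 <- gaussian_image(41, 41, 23, 18, total = 2e3, sigma = 1.5)
  lhs <- integrate_spot(3 * g1 + g2, c(20, 20))
  rhs <- 3 * integrate_spot(g1, c(20, 20)) + integrate_spot(g2, c(20, 20))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # box at the edge is refused
  expect_error(integrate_spot(img, c(3, 20)), "edge")
})

test_that("integration recovers the analytic in-circle Gaussian mass", {
  # spot width matching the simulator default, so the Gaussian tails in
  # the background annulus are negligible against the 2% tolerance
  V <- 1e4; sigma <- 1.5; w <- 5
  img <- gaussian_image(64, 64, 32, 32, total = V, sigma = sigma,
                        background = 11)
  meas <- integrate_spot(img, c(32, 32), box_half_width = w)
  # analytic mass inside the circle of radius w + 0.5
  R <- w + 0.5
  mass <- V * (1 - exp(-R^2 / (2 * sigma^2)))
  expect_lt(abs(meas - mass) / mass, 0.02)
  # off-grid centres stay within tolerance too
  img2 <- gaussian_image(64, 64, 31.6, 32.3, total = V, sigma = sigma,
                         background = 11)
  meas2 <- integrate_spot(img2, c(31.6, 32.3), box_half_width = w)
  expect_lt(abs(meas2 - mass) / mass, 0.02)
})

test_that("spot profiles report the Gaussian FWHM and the impulse limit", {
  img <- gaussian_image(41, 41, 20, 20, total = 2e4, sigma = 1.5,
                        background = 5)
  side <- matrix(5, 41, 41)
  fw <- spot_profile_fwhm(list(side, img, side), c(20, 20))
  expect_equal(fw$fwhm_x, 2.3548 * 1.5, tolerance = 0.5 / (2.3548 * 1.5))
  expect_equal(fw$fwhm_y, 2.3548 * 1.5, tolerance = 0.5 / (2.3548 * 1.5))
  # single-pixel impulse: one-sample width
  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  fwi <- spot_profile_fwhm(list(imp * 0, imp, imp * 0), c(20, 20))
  expect_equal(fwi$fwhm_x, 1)
  expect_equal(fwi$fwhm_y, 1)
  # flat profile flags as undefined
  flat <- spot_profile_fwhm(list(side, side, side), c(20, 20))
  expect_true(flat$flat)
})

test_that("rendered spots have the expected 3-5 px extent", {
  ser <- test_series()
  f <- which(ser$meta$tilt == 0)
  ser_r <- render_frames(ser, frames = (f - 1):(f + 1), poisson_noise = FALSE)
  tr <- ser_r$truth[ser_r$truth$frame == f, ]
  tr <- tr[order(-tr$I_spot), ][1:5, ]
  for (i in 1:5) {
    fw <- spot_profile_fwhm(lapply((f - 1):(f + 1), function(ff) {
      ser_r$frames[[as.character(ff)]]
    }), c(tr$x[i], tr$y[i]))
    expect_gte(fw$fwhm_x, 3); expect_lte(fw$fwhm_x, 5)
    expect_gte(fw$fwhm_y, 3); expect_lte(fw$fwhm_y, 5)
  }
})

test_that("noiseless integrated intensities track truth intensities", {
  ser <- simulate_tilt_series(orientation = c(25, -15, 60), seed = 6,
                              tilt_start = -4, tilt_stop = 4,
                              dose = dose_model(critical_dose = Inf),
                              poisson_noise = FALSE, render = TRUE)
  meas <- numeric(0); expected <- numeric(0)
  for (f in ser$meta$frame) {
    tr <- ser$truth[ser$truth$frame == f, ]
    if (!nrow(tr)) next
    img <- ser$frames[[as.character(f)]]
    ok <- round(tr$x) >= 5 & round(tr$x) <= ncol(img) - 6 &
      round(tr$y) >= 5 & round(tr$y) <= nrow(img) - 6
    tr <- tr[ok, ]
    meas <- c(meas, vapply(seq_len(nrow(tr)), function(i) {
      integrate_spot(img, c(tr$x[i], tr$y[i]))
    }, numeric(1)))
    expected <- c(expected, tr$I_true * tr$partiality)
  }
  expect_gt(length(meas), 100)
  expect_gt(stats::cor(meas, expected), 0.999)
})
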