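obs_tbl <- function(h, k, l, I) tibble::tibble(h = h, k = k, l = l, intensity = I)

test_that("maximum-intensity merging over symmetry orbits", {
  # singleton passes through unchanged
  m <- merge_max(obs_tbl(1, 2, 3, 10))
  expect_equal(nrow(m), 1)
  expect_equal(m$I, 10)
  expect_equal(m$n_obs, 1L)
  # the orbit maximum wins: {10, 14, 7} -> 14
  obs <- obs_tbl(c(1, 2, -1), c(2, 1, -2), c(3, 3, -3), c(10, 14, 7))
  m <- merge_max(obs)
  expect_equal(nrow(m), 1)
  expect_equal(m$I, 14)
  expect_equal(m$n_obs, 3L)
  # canonical representative respects h >= k >= 0, l >= 0
  expect_true(m$h >= m$k && m$k >= 0 && m$l >= 0)
  # uncertainty rules: SigI = sqrt(I), F = sqrt(I), SigF = sqrt(F)
  expect_equal(m$SigI, sqrt(14))
  expect_equal(m$F, sqrt(14))
  expect_equal(m$SigF, sqrt(sqrt(14)))
  # empty input gives an empty set
  expect_equal(nrow(merge_max(obs_tbl(integer(), integer(), integer(),
                                      numeric()))), 0)
})

test_that("merging is idempotent and order-invariant", {
  set.seed(61)
  n <- 400
  obs <- tibble::tibble(h = sample(-6:6, n, TRUE), k = sample(-6:6, n, TRUE),
                        l = sample(-4:4, n, TRUE),
                        intensity = rexp(n, 1 / 100))
  obs <- obs[!(obs$h == 0 & obs$k == 0 & obs$l == 0), ]
  m1 <- merge_max(obs)
  # idempotent: merging a merged set returns it unchanged
  m2 <- merge_max(m1)
  expect_equal(m2$I, m1$I)
  expect_equal(m2[, c("h", "k", "l")], m1[, c("h", "k", "l")],
               ignore_attr = TRUE)
  # order-invariant
  m3 <- merge_max(obs[sample(nrow(obs)), ])
  expect_equal(m3$I, m1$I)
  expect_equal(m3$h, m1$h)
})

test_that("amplitude conversion arithmetic and clamping", {
  a <- to_amplitudes(16)
  expect_equal(c(a$F, a$SigI, a$SigF), c(4, 4, 2))
  expect_equal(a$flag, "ok")
  expect_equal(to_amplitudes(0)$F, 0)
  neg <- to_amplitudes(-3)
  expect_equal(neg$F, 0)
  expect_equal(neg$flag, "negative")
})

test_that("merged partial intensities converge to truth as steps shrink", {
  # nested tilt grids (step 2 within 1 within 0.5), so each refinement
  # adds observations of the same reflections
  merged <- lapply(c(2, 1, 0.5), function(step) {
    ser <- simulate_tilt_series(orientation = c(15, -25, 40), seed = 7,
                                tilt_step = step,
                                dose = dose_model(critical_dose = Inf),
                                dmin = 3.5)
    merge_max(dplyr::rename(ser$truth[, c("h", "k", "l", "I_spot")],
                            intensity = "I_spot"))
  })
  truth <- sample_intensity_model(reference_cell(), dmin = 3.5, seed = 7)
  keys <- lapply(merged, function(m) paste(m$h, m$k, m$l))
  common <- Reduce(intersect, keys)
  expect_gt(length(common), 100)
  ratios <- vapply(seq_along(merged), function(i) {
    m <- merged[[i]][match(common, keys[[i]]), ]
    ix <- match(common, paste(truth$h, truth$k, truth$l))
    mean(m$I / truth$I[ix], na.rm = TRUE)
  }, numeric(1))
  # finer tilt sampling recovers more of the full intensity, monotonically
  expect_true(all(diff(ratios) >= 0))
  expect_gt(ratios[3], ratios[1])
})

test_that("completeness against the enumeration oracle", {
  cell <- reference_cell()
  uniq <- enumerate_hkl(cell, 2.9, 20, unique_only = TRUE)
  # a set containing every theoretical unique reflection is 100% complete
  full <- merge_max(tibble::tibble(h = uniq$h, k = uniq$k, l = uniq$l,
                                   intensity = 1))
  st <- completeness_stats(full, cell = cell)
  expect_equal(st$completeness, 1)
  expect_equal(st$n_unique_theoretical, nrow(uniq))
  # each unique observed exactly twice: multiplicity 2.0 by definition
  dup <- rbind(uniq[, 1:3], uniq[, 1:3])
  st2 <- completeness_stats(merge_max(tibble::tibble(h = dup$h, k = dup$k,
                                                     l = dup$l,
                                                     intensity = 1)),
                            cell = cell)
  expect_equal(st2$multiplicity, 2)
  # half the reflections: completeness 0.5 and sane shells
  half <- uniq[seq_len(nrow(uniq)) %% 2 == 0, ]
  sth <- completeness_stats(merge_max(tibble::tibble(h = half$h, k = half$k,
                                                     l = half$l,
                                                     intensity = 1)),
                            cell = cell)
  expect_equal(sth$completeness, nrow(half) / nrow(uniq), tolerance = 1e-12)
  expect_true(all(sth$shells$completeness >= 0 & sth$shells$completeness <= 1,
                  na.rm = TRUE))
  expect_equal(sum(sth$shells$n_theory), nrow(uniq))
})

test_that("structure-factor files round-trip at full precision", {
  set.seed(62)
  uniq <- enumerate_hkl(reference_cell(), 4, 20, unique_only = TRUE)
  pick <- uniq[sample(nrow(uniq), 100), ]
  m <- merge_max(tibble::tibble(h = pick$h, k = pick$k, l = pick$l,
                                intensity = rexp(100, 1 / 500)),
                 cell = reference_cell(), wavelength = 0.0251)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_sf_file(m, path)
  lines <- readLines(path)
  # commented header carries cell, symmetry and wavelength
  expect_true(any(grepl("^# cell 77 77 37 90 90 90$", lines)))
  expect_true(any(grepl("^# symmetry P43212$", lines)))
  expect_true(any(grepl("^# wavelength 0.0251$", lines)))
  # fixed column order, byte for byte
  expect_equal(lines[which(!grepl("^#", lines))[1]], "h k l F SIGF I SIGI")
  back <- read_sf_file(path)
  expect_equal(back$I, m$I)
  expect_equal(back$F, m$F)
  expect_equal(back$SigF, m$SigF)
  expect_equal(back$SigI, m$SigI)
  expect_equal(back[, c("h", "k", "l")], m[, c("h", "k", "l")],
               ignore_attr = TRUE)
  cl <- attr(back, "cell")
  expect_equal(c(cl$a, cl$b, cl$c), c(77, 77, 37))
  expect_equal(cl$space_group, "P43212")
  # malformed rows are reported with their line number
  writeLines(c(lines, "1 2 x 4"), path)
  expect_error(read_sf_file(path), paste0("line ", length(lines) + 1))
})

test_that("perturbation modes satisfy their invariants", {
  set.seed(63)
  uniq <- enumerate_hkl(reference_cell(), 4, 20, unique_only = TRUE)
  m <- merge_max(tibble::tibble(h = uniq$h, k = uniq$k, l = uniq$l,
                                intensity = rexp(nrow(uniq), 1 / 300)))
  # mode 1: uniform draws within [min, max] of the input
  p1 <- perturb_dataset(m, 1, seed = 5)
  expect_gte(min(p1$I), min(m$I))
  expect_lte(max(p1$I), max(m$I))
  expect_false(identical(p1$I, m$I))
  # mode 2: intensity multiset preserved, indices unchanged
  p2 <- perturb_dataset(m, 2, seed = 5)
  expect_equal(sort(p2$I), sort(m$I))
  expect_equal(p2[, c("h", "k", "l")], m[, c("h", "k", "l")],
               ignore_attr = TRUE)
  # mode 3: donor intensities recycled over the same index set
  donor <- rexp(100, 1 / 50)
  p3 <- perturb_dataset(m, 3, seed = 5, donor_intensities = donor)
  expect_equal(p3$I, rep_len(donor, nrow(m)))
  expect_error(perturb_dataset(m, 3, seed = 5), "donor")
  # mode 4: every intensity within +/-35% of its input
  p4 <- perturb_dataset(m, 4, seed = 5)
  expect_true(all(abs(p4$I / m$I - 1) <= 0.35))
  expect_error(perturb_dataset(m, 7), "mode")
  # amplitudes recomputed from the perturbed intensities
  expect_equal(p4$F, sqrt(pmax(p4$I, 0)))
})
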