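test_that("rate maps are definitional: count over occupancy", {
  tr <- stationary_trajectory(2, x = 10, y = 10)
  # one spike, 2 s occupancy in one bin, no smoothing -> 0.5 spikes/s
  map <- compute_rate_map(0.5, tr, bin = 3, sigma_smooth = 0)
  expect_equal(map$rate[4, 4], 0.5, tolerance = 0.02)
  expect_true(all(is.na(map$rate[map$occupancy == 0])))

  map0 <- compute_rate_map(numeric(0), tr, sigma_smooth = 0)
  expect_true(all(map0$rate[!is.na(map0$rate)] == 0))
  expect_error(compute_rate_map(1, tr[1, , drop = FALSE]), "too short")
})

test_that("unsmoothed rate maps conserve total spike mass", {
  tr <- synthesize_trajectory(120, seed = 21)
  spk <- tr$t[seq(5, nrow(tr), by = 17)]   # spikes at sample times
  map <- compute_rate_map(spk, tr, sigma_smooth = 0)
  mass <- sum(map$rate * map$occupancy, na.rm = TRUE)
  expect_equal(mass, length(spk), tolerance = 1e-9)
})

test_that("homogeneous Poisson firing yields a flat map at the true rate", {
  set.seed(31)
  tr <- synthesize_trajectory(600, seed = 31)
  lambda <- 4
  n <- rpois(1, lambda * 600)
  spk <- sort(runif(n, 0, 600))
  map <- compute_rate_map(spk, tr)
  expect_equal(mean(map$rate, na.rm = TRUE), lambda, tolerance = 0.12)
  expect_lt(sd(map$rate, na.rm = TRUE) / lambda, 0.5)
})

test_that("autocorrelograms are normalized, symmetric, and find stripe periods", {
  stripes <- matrix(rep(c(2, 0, 0, 0, 0), length.out = 25 * 25), 25, 25,
                    byrow = TRUE)  # vertical stripes, period 5 in x
  stripes <- stripes + matrix(runif(625, 0, 0.01), 25, 25)
  ac <- spatial_autocorrelogram(stripes, bin = 3, min_overlap = 10)
  ctr <- (dim(ac$ac) + 1) / 2
  expect_equal(ac$ac[ctr[1], ctr[2]], 1)
  expect_equal(ac$ac, ac$ac[rev(seq_len(nrow(ac$ac))), rev(seq_len(ncol(ac$ac)))],
               tolerance = 1e-9)
  expect_gt(ac$ac[ctr[1], ctr[2] + 5], 0.9)
  expect_gt(ac$ac[ctr[1], ctr[2] - 5], 0.9)
  expect_lt(ac$ac[ctr[1], ctr[2] + 2], 0.2)
  expect_warning(spatial_autocorrelogram(matrix(1, 10, 10), bin = 3),
                 "constant")
})

test_that("grid score separates hexagonal, isotropic and square structure", {
  hexmap <- bump_map(hex_centers(a = 40), sigma = 7, extent = 150)
  ac_hex <- spatial_autocorrelogram(hexmap, bin = 3, min_overlap = 10)
  expect_gt(grid_score(ac_hex), 0.8)

  # radially symmetric autocorrelogram: all rotations equal, score ~ 0
  n <- 61; ctr <- 31
  r <- sqrt(outer((1:n - ctr)^2, rep(1, n)) + outer(rep(1, n), (1:n - ctr)^2))
  ac_iso <- exp(-r / 12) * cos(2 * pi * r / 16)
  expect_lt(abs(grid_score(ac_iso)), 0.1)

  sq_centers <- as.matrix(expand.grid(x = seq(-40, 190, by = 40),
                                      y = seq(-40, 190, by = 40)))
  sqmap <- bump_map(sq_centers, sigma = 7, extent = 150)
  ac_sq <- spatial_autocorrelogram(sqmap, bin = 3, min_overlap = 10)
  expect_lt(grid_score(ac_sq), 0)
})

test_that("grid score is invariant to uniform rate scaling", {
  hexmap <- bump_map(hex_centers(a = 40), sigma = 7, extent = 150)
  ac1 <- spatial_autocorrelogram(hexmap, bin = 3, min_overlap = 10)
  ac2 <- spatial_autocorrelogram(hexmap * 7.3, bin = 3, min_overlap = 10)
  expect_equal(grid_score(ac1), grid_score(ac2), tolerance = 1e-9)
})

test_that("field detection recovers the Gaussian level-set diameter", {
  m <- bump_map(matrix(c(22.5, 22.5), 1), sigma = 4, extent = 45, bin = 1.5)
  map <- as_rate_map(m, bin = 1.5)
  f <- detect_fields(map)
  expect_equal(nrow(f), 1)
  # 20% level set of a Gaussian: diameter 2*sigma*sqrt(2 ln 5)
  expect_equal(f$diameter, 2 * 4 * sqrt(2 * log(5)), tolerance = 0.15)
  expect_equal(f$cx, 22.5, tolerance = 1.5)
  expect_equal(f$cy, 22.5, tolerance = 1.5)

  expect_equal(nrow(detect_fields(as_rate_map(matrix(1, 15, 15)))), 0)

  two <- bump_map(matrix(c(10, 10, 35, 35), 2, byrow = TRUE), sigma = 4,
                  extent = 45, bin = 1.5)
  expect_equal(nrow(detect_fields(as_rate_map(two, bin = 1.5))), 2)
})

test_that("merged fields are split at the watershed between peaks", {
  # two bumps close enough that their 20% contours fuse
  two <- bump_map(matrix(c(15, 22.5, 30, 22.5), 2, byrow = TRUE), sigma = 4.5,
                  extent = 45, bin = 1.5)
  f <- detect_fields(as_rate_map(two, bin = 1.5))
  expect_equal(nrow(f), 2)
  expect_equal(sort(f$cx), c(15, 30), tolerance = 2)
})

test_that("field spacing and orientation recover a constructed 47-cm lattice", {
  hexmap <- bump_map(hex_centers(a = 47), sigma = 7, extent = 160)
  ac <- spatial_autocorrelogram(hexmap, bin = 3, min_overlap = 10)
  sp <- field_spacing(ac)
  expect_equal(sp$spacing, 47, tolerance = 3)   # within one bin
  expect_equal(sp$orientation, 0, tolerance = 2)

  rot <- bump_map(hex_centers(a = 47, angle_deg = 15), sigma = 7, extent = 160)
  ac_r <- spatial_autocorrelogram(rot, bin = 3, min_overlap = 10)
  sp_r <- field_spacing(ac_r)
  expect_equal(sp_r$spacing, 47, tolerance = 3)
  expect_equal(sp_r$orientation, 15, tolerance = 2)

  set.seed(12)
  noise <- matrix(runif(900), 30, 30)
  ac_n <- spatial_autocorrelogram(noise, bin = 3, min_overlap = 10)
  expect_true(is.na(field_spacing(ac_n)$spacing))
})

test_that("spacing estimates tighten as bins shrink", {
  errs <- sapply(c(4, 2), function(b) {
    m <- bump_map(hex_centers(a = 44), sigma = 7, extent = 160, bin = b)
    ac <- spatial_autocorrelogram(m, bin = b, min_overlap = 10)
    abs(field_spacing(ac)$spacing - 44)
  })
  expect_lte(errs[2], errs[1] + 0.5)
  expect_lt(errs[2], 2.5)
})
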