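# Active-contour energies, greedy evolution and the entropy stopping rule.

unit_square_snake <- function(alpha = 1, beta = 0, ...) {
  # regular 4-gon of circumradius 1: |v_s|^2 = 2 for every edge
  pts <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
  snake(pts, alpha = alpha, beta = beta, ...)
}

test_that("internal energy matches the closed form for the unit square", {
  expect_equal(internal_energy(unit_square_snake(alpha = 1, beta = 0)), 4)
  expect_equal(internal_energy(unit_square_snake(alpha = 0, beta = 0)), 0)
})

test_that("alpha term is homogeneous of degree 2 in coordinate scaling", {
  pts <- cbind(c(2, 7, 6, 1), c(1, 2, 8, 6))
  e1 <- internal_energy(snake(pts, alpha = 1.3, beta = 0))
  e3 <- internal_energy(snake(3 * pts, alpha = 1.3, beta = 0))
  expect_equal(e3, 9 * e1)
})

test_that("snake constructor validates its input", {
  expect_error(snake(cbind(1:3, 1:3)), class = "lq_invalid_input")
  expect_error(snake(cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), alpha = -1),
               class = "lq_invalid_input")
})

test_that("external energy field is non-positive with minima on edges", {
  f0 <- external_energy_field(matrix(50, 10, 10))
  expect_true(all(f0$external == 0))
  step <- cbind(matrix(0, 10, 5), matrix(255, 10, 5))
  fs <- external_energy_field(step, smooth_sigma = 0)
  expect_true(all(fs$external <= 0))
  # most negative values straddle the step between columns 5 and 6
  expect_true(all(apply(fs$external, 1, which.min) %in% 5:6))
  set.seed(9)
  fr <- external_energy_field(matrix(runif(100, 0, 255), 10, 10))
  expect_true(all(fr$external <= 0))
})

test_that("total energy decomposes as internal + external + constraint", {
  zero <- external_energy_field(matrix(0, 30, 30))
  sq <- snake(cbind(c(16, 14, 14, 16), c(14, 14, 16, 16)), alpha = 0, beta = 0)
  expect_equal(total_energy(sq, zero), 0)
  sq2 <- snake(10 + cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), alpha = 1, beta = 0)
  expect_equal(total_energy(sq2, zero), 4)
  withcon <- zero; withcon$con <- matrix(5, 30, 30)
  expect_equal(total_energy(sq2, withcon), 4 + 4 * 5)
})

test_that("elasticity-only evolution contracts the contour to a point", {
  zero <- external_energy_field(matrix(0, 20, 20))
  sn <- snake(cbind(c(6, 14, 14, 6), c(6, 6, 14, 14)), alpha = 1, beta = 0)
  areas <- numeric(0)
  for (i in 1:15) {
    sn <- evolve(sn, zero, 1L)
    areas <- c(areas, abs(laryngoquant:::polygon_area(sn$points[, 1], sn$points[, 2])))
  }
  expect_lt(areas[15], 1)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("a snake on a high-gradient ring is stationary", {
  g <- matrix(0, 40, 40)
  yy <- row(g); xx <- col(g)
  g[(xx - 20)^2 + (yy - 20)^2 <= 100] <- 255
  field <- external_energy_field(g)
  theta <- seq(0, 2 * pi, length.out = 17)[1:16]
  pts <- cbind(20 + 10 * cos(theta), 20 + 10 * sin(theta))
  sn <- evolve(snake(pts, alpha = 1, beta = 0.5), field, 5L)
  radii <- sqrt((sn$points[, 1] - 20)^2 + (sn$points[, 2] - 20)^2)
  expect_true(all(abs(radii - 10) <= 1.5))
})

test_that("greedy evolution never increases the total energy", {
  ph <- make_phantom(phantom_params(seed = 2))
  g <- rgb_to_gray(ph$image)
  field <- external_energy_field(g)
  pts <- laryngoquant:::resample_polygon(c(80, 180, 180, 80), c(40, 40, 120, 120), 60)
  for (gam in c(0, -40, 25)) {
    sn <- evolve(snake(pts, alpha = 1, beta = 0.5, gamma = gam), field, 15L)
    expect_true(all(diff(attr(sn, "energy_trace")) <= 1e-9))
  }
})

test_that("region entropy matches analytic histograms", {
  g <- matrix(100, 8, 8)
  m <- matrix(TRUE, 8, 8)
  expect_equal(region_entropy(g, m), 0)
  g2 <- matrix(c(10, 200), 8, 8)  # two levels, equal proportions
  expect_equal(region_entropy(g2, m), 1)
  g3 <- matrix(0:255, 16, 16)     # uniform over all 256 levels
  expect_equal(region_entropy(g3, matrix(TRUE, 16, 16)), 8)
  expect_error(region_entropy(g, matrix(FALSE, 8, 8)), class = "lq_invalid_input")
})

test_that("entropy is invariant to mask translation and pixel permutation", {
  set.seed(21)
  g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  m <- matrix(FALSE, 20, 20); m[3:8, 3:8] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[11:16, 12:17] <- TRUE
  g2 <- g
  g2[m2] <- sample(g[m])  # same multiset of values, permuted, elsewhere
  expect_equal(region_entropy(g2, m2), region_entropy(g, m))
})

test_that("adaptive stopping on a homogeneous image hits min_iter", {
  g <- matrix(80, 60, 60)
  field <- external_energy_field(g)
  pts <- laryngoquant:::resample_polygon(c(15, 45, 45, 15), c(15, 15, 45, 45), 40)
  ad <- adaptive_evolve(snake(pts, alpha = 1, beta = 0), field, g)
  expect_identical(ad$n_star, 13L)
  expect_true(all(ad$entropy_diffs[-1] == 0))
})

test_that("a contour degenerating before min_iter signals an error", {
  g <- matrix(80, 30, 30)
  field <- external_energy_field(g)
  pts <- cbind(c(14, 18, 18, 14), c(14, 14, 18, 18))
  expect_error(adaptive_evolve(snake(pts, alpha = 2, beta = 0), field, g),
               class = "lq_degenerate_contour")
})

test_that("mask_to_snake recovers a convex region boundary", {
  m <- matrix(FALSE, 30, 30); m[10:20, 8:22] <- TRUE
  sn <- mask_to_snake(m, n_points = 40)
  filled <- snake_mask(sn, 30, 30)
  expect_gt(dice(filled, m), 0.9)
  expect_error(mask_to_snake(matrix(FALSE, 5, 5)), class = "lq_invalid_input")
})
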