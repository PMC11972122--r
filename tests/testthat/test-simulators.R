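test_that("1D scenario profiles match their definitions", {
  expect_equal(simulate_1d("shaping", 2), c(0, 0, 3, 2, 1))
  expect_equal(simulate_1d("shifting", 1), c(0, 0, 1, 0, 0))
  expect_equal(simulate_1d("spreading", 3), rep(1, 5))
  expect_equal(simulate_1d("propagating", 3), c(1, 0, 0, 0, 1))
  expect_error(simulate_1d("shifting", 4), "unknown stage")
  expect_error(simulate_1d("shifting", 0), "unknown stage")

  # the shaping profile with densities 3,2,1 has SNR 2/3; the uniform
  # spreading end-state scores 0 on both metrics; centered starts are symmetric
  expect_equal(signal_noise_ratio(di_derivative(simulate_1d("shaping", 2)))$snr, 2 / 3)
  expect_equal(degree_of_inequality(simulate_1d("spreading", 3)), 0)
  expect_equal(cwsnr(simulate_1d("spreading", 3))$cwsnr, 0)
  expect_equal(degree_of_inequality(simulate_1d("shifting", 1)), 0)

  # shaping stages are ranked b2 > b1 > b3 by CWSNR
  cw <- vapply(1:3, function(st) cwsnr(simulate_1d("shaping", st))$cwsnr, numeric(1))
  expect_gt(cw[2], cw[1])
  expect_gt(cw[1], cw[3])
})

test_that("the ten distinct scenarios are separated with accuracy 0.9", {
  profiles <- scenario_profiles_1d()
  expect_length(profiles, 10L)
  expect_length(unique(lapply(profiles, identity)), 10L)
  sep <- metric_separation(profiles)
  expect_identical(sep$n_distinct, 9L)
  expect_equal(sep$accuracy, 0.9)
  # the collapsed pair is the uniform spread and the endpoint propagation:
  # both are symmetric (DI = 0) with no center-weighted signal (CWSNR = 0)
  tab <- sep$table
  tied <- tab[abs(tab$di) < 1e-9 & abs(tab$cwsnr) < 1e-9, "scenario"]
  expect_setequal(tied, c("c3", "d3"))
})

test_that("2D circular propagation forms the specified annulus", {
  m1 <- simulate_2d("circular_propagation", t = 1)
  expect_equal(dim(m1), c(51L, 51L))
  expect_equal(m1[26, 26], 5000)
  expect_equal(sum(m1 > 0), 1L)

  m2 <- simulate_2d("circular_propagation", t = 2)
  expect_equal(unique(m2[m2 > 0]), 1000) # 5000 / 5
  nz <- which(m2 > 0, arr.ind = TRUE)
  d <- sqrt((nz[, 1] - 26)^2 + (nz[, 2] - 26)^2)
  expect_true(all(d >= 4 & d <= 5))
  # every on-annulus cell is filled
  expect_equal(sum(m2 > 0), sum({
    dx <- outer(rep(1, 51), 1:51 - 26)
    dy <- outer(1:51 - 26, rep(1, 51))
    dd <- sqrt(dx^2 + dy^2)
    dd >= 4 & dd <= 5
  }))
  expect_error(simulate_2d("circular_propagation", t = 5), "1..4")
})

test_that("every circular-propagation frame is symmetric with positive coverage", {
  for (t in 1:4) {
    m <- simulate_2d("circular_propagation", t = t)
    expect_equal(sii(m), 0, tolerance = 1e-12)
    expect_gt(sci(m), 0)
  }
})

test_that("the sector mask keeps right-pointing cells only", {
  m <- simulate_2d("circular_sector", t = 4) # annulus at distance 12..15
  # (dx, dy) = (15, 0): on the annulus and inside the sector
  expect_gt(m[26, 26 + 15], 0)
  # (dx, dy) = (0, 15): on the annulus but masked
  expect_equal(m[26 + 15, 26], 0)
  expect_equal(m[26 - 15, 26], 0)
  nz <- which(m > 0, arr.ind = TRUE)
  dx <- nz[, 2] - 26
  dy <- nz[, 1] - 26
  expect_true(all(dx >= dy & dx >= -(dy + 1)))
})

test_that("translation occupies the inner-to-outer span on the center row", {
  m1 <- simulate_2d("translation", t = 1)
  expect_equal(sii(m1), 0)
  m2 <- simulate_2d("translation", t = 2)
  nz <- which(m2 > 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == 26))
  expect_equal(sort(nz[, 2]), c(30L, 31L)) # distances 4..5 to the right
  expect_equal(unique(m2[m2 > 0]), 1000)

  # directional models grow increasingly dissymmetric over time
  for (model in c("translation", "circular_with_direction")) {
    s <- vapply(1:4, function(t) sii(simulate_2d(model, t = t)), numeric(1))
    expect_true(all(diff(s) > 0))
  }
})

test_that("rotation is exact at quarter turns and mass-conserving elsewhere", {
  m <- simulate_2d("translation", t = 2)
  expect_identical(rotate_map(m, 0), m)
  expect_identical(rotate_map(m, 360), m)
  r <- m
  for (i in 1:4) r <- rotate_map(r, 90)
  expect_equal(r, m)

  # a half turn exactly negates the x-axis degree of inequality
  di0 <- degree_of_inequality(project(m, "x"))
  di180 <- degree_of_inequality(project(rotate_map(m, 180), "x"))
  expect_equal(di180, -di0)

  for (a in c(30, 45, 137.5, 300)) {
    rm <- rotate_map(m, a)
    expect_true(all(rm >= 0))
    expect_equal(sum(rm), sum(m), tolerance = 1e-9)
  }
  expect_error(rotate_map(matrix(1, 2, 3), 90), "square")
})

test_that("rotation sweeps show rotation-robust SII but angle-dependent DIx", {
  sw <- rotation_sweep("translation", t = 2)
  expect_equal(nrow(sw$per_angle), 12L)
  expect_equal(sw$per_angle$angle, seq(0, 330, by = 30))
  svar <- sw$summary$variance[sw$summary$metric == "sii"]
  expect_lt(svar, 1e-6)
  expect_lt(abs(sw$summary$mean[sw$summary$metric == "di_x"]), 1e-9)
  # DIx swings with the rotation angle even though SII stays put
  expect_gt(sw$summary$variance[sw$summary$metric == "di_x"], 0.005)

  sw4 <- rotation_sweep("translation", t = 4)
  first <- sw4$per_angle[1, ]
  expect_equal(first$di_x, -first$sii, tolerance = 1e-12)
})

test_that("random matrices are reproducible and leave the RNG state alone", {
  a <- random_matrix(40, seed = 0)
  b <- random_matrix(40, seed = 0)
  expect_identical(a, b)
  expect_false(identical(a, random_matrix(40, seed = 1)))
  expect_true(all(a >= 0))

  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(random_matrix(10, seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("the benchmark harness records one timing per size and repetition", {
  bm <- benchmark_metrics(dims = c(50L, 100L), reps = 2L, seed = 0L)
  expect_equal(nrow(bm), 4L)
  expect_true(all(bm$seconds >= 0))
  expect_setequal(unique(bm$dim), c(50L, 100L))
})
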