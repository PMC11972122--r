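test_that("degree of inequality reproduces the worked single-unit examples", {
  expect_identical(degree_of_inequality(c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0)), -0.5)
  expect_identical(
    degree_of_inequality(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0)),
    -0.5
  )
  expect_equal(degree_of_inequality(rep(1, 5)), 0)
  # single unit at 1-based position p of n has DI = (n + 1 - 2p) / n
  for (n in c(3L, 5L, 10L, 17L)) {
    for (p in seq_len(n)) {
      x <- numeric(n)
      x[p] <- 1
      expect_equal(degree_of_inequality(x), (n + 1 - 2 * p) / n)
    }
  }
  expect_equal(degree_of_inequality(c(1, 0, 0, 0, 0)), 0.8)
})

test_that("degree of inequality matches the brute-force cumulative-sum oracle", {
  set.seed(11)
  for (i in 1:50) {
    x <- random_profile(sample(2:40, 1))
    expect_equal(degree_of_inequality(x), brute_di(x), tolerance = 1e-12)
  }
})

test_that("DI is scale invariant, antisymmetric under reversal, and bounded", {
  set.seed(7)
  for (i in 1:50) {
    x <- random_profile(sample(2:60, 1))
    di <- degree_of_inequality(x)
    expect_equal(degree_of_inequality(3.7 * x), di, tolerance = 1e-12)
    expect_equal(degree_of_inequality(0.001 * x), di, tolerance = 1e-12)
    expect_equal(degree_of_inequality(rev(x)), -di, tolerance = 1e-12)
    expect_gte(di, -1)
    expect_lte(di, 1)
  }
})

test_that("DI is preserved under pixel duplication (resolution doubling)", {
  set.seed(13)
  for (i in 1:25) {
    x <- random_profile(sample(2:40, 1))
    n <- length(x)
    drift <- abs(degree_of_inequality(duplicate_pixels(x)) -
                   degree_of_inequality(x))
    expect_lte(drift, 1 / n)
  }
})

test_that("invalid profiles are rejected", {
  expect_error(degree_of_inequality(numeric(0)), "length")
  expect_error(degree_of_inequality(c(1, -2, 3)), "negative")
  expect_error(degree_of_inequality(c(1, NA, 3)), "missing")
  expect_error(di_derivative(c(-1, 1)), "negative")
  expect_identical(degree_of_inequality(c(0, 0, 0)), 0)
})

test_that("the DI derivative equals prefix-DI finite differences", {
  expect_equal(di_derivative(c(0, 0, 3, 2, 1)),
               c(-0.2, -0.2, 0.3, 2 / 15, -1 / 30), tolerance = 1e-12)
  expect_identical(di_derivative(rep(4, 4)), rep(0, 4))
  expect_equal(di_derivative(c(5, 0, 0, 0, 0)), c(0.8, -0.2, -0.2, -0.2, -0.2))
  set.seed(19)
  for (i in 1:40) {
    x <- random_profile(sample(2:50, 1))
    d <- di_derivative(x)
    fd <- vapply(seq_along(x), function(k) {
      prefix_di(x, k) - prefix_di(x, k - 1)
    }, numeric(1))
    expect_equal(d, fd, tolerance = 1e-12)
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
  expect_identical(di_derivative(numeric(3)), numeric(3))
})

test_that("signal/noise unit counting behaves as specified", {
  r <- signal_noise_ratio(di_derivative(c(0, 0, 3, 2, 1)))
  expect_identical(r$c_signal, 2L)
  expect_identical(r$c_noise, 3L)
  expect_equal(r$snr, 2 / 3)

  r_unif <- signal_noise_ratio(di_derivative(rep(2, 6)))
  expect_identical(r_unif$c_signal, 0L)
  expect_equal(r_unif$snr, 0)

  r_one <- signal_noise_ratio(di_derivative(c(5, 0, 0, 0, 0)))
  expect_identical(r_one$c_signal, 1L)
  expect_identical(r_one$c_noise, 4L)
  expect_equal(r_one$snr, 0.25)

  set.seed(23)
  for (i in 1:20) {
    d <- di_derivative(random_profile(sample(2:30, 1)))
    r <- signal_noise_ratio(d)
    expect_identical(r$c_signal + r$c_noise, length(d))
  }
  # all-positive input triggers the finite cap with a warning
  expect_warning(r_cap <- signal_noise_ratio(c(0.1, 0.2)), "capped")
  expect_identical(r_cap$snr, 2L)
})

test_that("center weights form a symmetric semicircle, 1 at center, 0 at ends", {
  expect_identical(center_weights(1), 1)
  expect_equal(center_weights(3), c(0, 1, 0))
  expect_equal(center_weights(5), c(0, sqrt(3) / 2, 1, sqrt(3) / 2, 0))
  for (n in c(4L, 6L, 7L, 11L, 20L)) {
    w <- center_weights(n)
    expect_equal(w, rev(w))
    expect_equal(w[1], 0)
    expect_equal(w[n], 0)
    if (n %% 2 == 1) expect_equal(max(w), 1)
    # non-increasing away from the center
    half <- w[seq_len(ceiling(n / 2))]
    expect_true(all(diff(half) >= -1e-12) || all(half == cummax(half)))
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(center_weights(0), "integer")
})

test_that("CWSNR composes SNR, rectified derivative and center weights", {
  dec <- cwsnr(c(0, 0, 3, 2, 1))
  expect_s3_class(dec, "axis_decomposition")
  expect_equal(dec$v, pmax(dec$d_di, 0))
  # independent brute-force re-derivation from the raw profile
  x <- c(0, 0, 3, 2, 1)
  expected <- (2 / 3) * (0.3 * 1 + (2 / 15) * sqrt(3) / 2)
  expect_equal(dec$cwsnr, expected, tolerance = 1e-12)
  expect_equal(dec$cwsnr, 0.27698, tolerance = 1e-4)

  expect_equal(cwsnr(rep(5, 9))$cwsnr, 0)
  expect_equal(cwsnr(numeric(7))$cwsnr, 0)
  set.seed(29)
  for (i in 1:30) {
    d <- cwsnr(random_profile(sample(2:40, 1)))
    expect_gte(d$cwsnr, 0)
  }
})

test_that("comparator indices follow their closed forms", {
  expect_equal(alternative_metric(rep(1, 4), "shannon"), 2)
  expect_equal(alternative_metric(c(0, 0, 8), "shannon"), 0)
  set.seed(31)
  for (i in 1:20) {
    x <- random_profile(sample(2:30, 1))
    expect_equal(alternative_metric(x, "simpson"),
                 1 - alternative_metric(x, "hhi"), tolerance = 1e-12)
  }
  expect_equal(alternative_metric(c(2, 2, 2, 2), "atkinson"), 0)
  expect_gt(alternative_metric(c(10, 1, 1), "atkinson"), 0)

  # Theil oracle: literal transcription of the shifted-mean formula
  x <- c(1, 2, 3)
  eps <- 0.01
  xe <- x + eps
  mu <- mean(xe)
  expect_equal(alternative_metric(x, "theil"),
               sum((xe / mu) * log(xe / mu)) / length(x), tolerance = 1e-12)
  expect_gt(alternative_metric(x, "theil"), 0)
  expect_equal(alternative_metric(c(5, 5, 5), "theil"), 0)

  expect_warning(z <- alternative_metric(c(0, 0), "shannon"), "all-zero")
  expect_identical(z, 0)
  expect_error(alternative_metric(c(1, 2), "theil", theil_epsilon = 0), "positive")
  expect_error(alternative_metric(c(1, 2), "atkinson", atkinson_aversion = 1), "0, 1")
})
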