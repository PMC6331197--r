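test_that("a single class spans the full range and decodes to its midpoint", {
  b <- build_binning(1, mu = 996, sigma = 300)
  expect_equal(b$bounds, c(392, 1960))
  expect_equal(class_to_pressure(1, b), (392 + 1960) / 2)  # 1176 Pa
  expect_equal(pressure_to_class(c(392, 1000, 1959.9), b), rep(1L, 3))
})

test_that("bounds partition the range with equal Gaussian mass per class", {
  for (K in c(2, 10, 101, 1007)) {
    b <- build_binning(K, mu = 996, sigma = 300)
    expect_equal(b$bounds[1], 392)
    expect_equal(b$bounds[K + 1], 1960)
    expect_true(all(diff(b$bounds) > 0))
    mass <- diff(pnorm(b$bounds, 996, 300))
    expect_equal(mass, rep(mass[1], K), tolerance = 1e-9)
  }
})

test_that("the K=2 interior bound matches a bisection oracle on the Gaussian CDF", {
  mu <- 996; sigma <- 300
  b <- build_binning(2, mu, sigma)
  # oracle: bisection for the mid-mass quantile between the truncation bounds
  target <- (pnorm(392, mu, sigma) + pnorm(1960, mu, sigma)) / 2
  lo <- 392; hi <- 1960
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pnorm(mid, mu, sigma) < target) lo <- mid else hi <- mid
  }
  expect_equal(b$bounds[2], (lo + hi) / 2, tolerance = 1e-8)
})

test_that("membership is half-open with clamping at the edges", {
  b <- build_binning(10, mu = 996, sigma = 300)
  # a label exactly on an interior bound belongs to the upper class
  for (i in 2:10) expect_equal(pressure_to_class(b$bounds[i], b), i)
  expect_equal(pressure_to_class(392, b), 1L)
  expect_equal(pressure_to_class(100, b), 1L)    # below range clamps
  expect_equal(pressure_to_class(1960, b), 10L)  # at/above range clamps
  expect_equal(pressure_to_class(5000, b), 10L)
})

test_that("pressure_to_class is non-decreasing and decoding stays within one class width", {
  b <- build_binning(101, mu = 996, sigma = 300)
  y <- seq(392, 1959.99, length.out = 4001)
  cls <- pressure_to_class(y, b)
  expect_true(all(diff(cls) >= 0))
  dec <- class_to_pressure(cls, b)
  expect_true(all(abs(dec - y) <= max(class_widths(b))))
  # midpoint decodes back into its own class
  expect_equal(pressure_to_class(dec, b), cls)
})

test_that("labels drawn from the balancing Gaussian fill classes uniformly", {
  set.seed(5)
  mu <- 996; sigma <- 300; n <- 1e5; K <- 10
  y <- numeric(0)
  while (length(y) < n) {
    p <- rnorm(n, mu, sigma)
    y <- c(y, p[p >= 392 & p < 1960])
  }
  y <- y[seq_len(n)]
  b <- build_binning(K, mu, sigma)
  counts <- tabulate(pressure_to_class(y, b), K)
  expected <- n / K
  sd3 <- 3 * sqrt(n * (1 / K) * (1 - 1 / K))
  expect_true(all(abs(counts - expected) <= sd3))
  # midpoint decoding is unbiased to second order in the class width: the
  # signed-error-to-spread ratio collapses as granularity grows, and is
  # negligible at the default 1007 classes
  ratio <- vapply(c(10, 101, 1007), function(K) {
    bk <- build_binning(K, mu, sigma)
    err <- class_to_pressure(pressure_to_class(y, bk), bk) - y
    abs(mean(err)) / sd(err)
  }, 0)
  expect_true(all(diff(ratio) < 0))
  expect_lt(ratio[3], 0.01)
})

test_that("degenerate binning requests are rejected", {
  expect_error(build_binning(0, 996, 300), "K")
  expect_error(build_binning(10, 996, 0), "sigma")
  expect_error(build_binning(10, 996, 300, lo = 2000, hi = 1000), "lo")
  expect_error(class_to_pressure(11, build_binning(10, 996, 300)), "range")
})
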