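test_that("sampled configurations respect the bounds and the pressure Gaussian", {
  cfg <- generator_config()
  set.seed(21)
  qs <- sample_parameters(10000, cfg)
  b <- cfg$bounds
  for (j in colnames(b)) {
    expect_true(all(qs[, j] >= b["lower", j]))
    expect_true(all(qs[, j] <= b["upper", j]))
  }
  # oracle: truncated-normal mean by numerical integration over [400, 2000] Pa
  mass <- integrate(function(x) dnorm(x, 996, 300), 400, 2000)$value
  mu_trunc <- integrate(function(x) x * dnorm(x, 996, 300), 400, 2000)$value / mass
  m2 <- integrate(function(x) x^2 * dnorm(x, 996, 300), 400, 2000)$value / mass
  sd_trunc <- sqrt(m2 - mu_trunc^2)
  labels <- qs[, "QPs"] * 800
  expect_lt(abs(mean(labels) - mu_trunc), 3 * sd_trunc / sqrt(nrow(qs)))
  expect_equal(sample_parameters(0, cfg), matrix(NA_real_, 0, 6,
               dimnames = list(NULL, colnames(b))), ignore_attr = TRUE)
})

test_that("label calibration is a checked multiplicative factor", {
  expect_equal(calibrate_label(800, 1.0), 800)
  expect_equal(calibrate_label(800, 1.25), 1000)
  expect_error(calibrate_label(800, 0), "positive")
  expect_error(calibrate_label(800, -2), "positive")
})

test_that("additive noise is calibrated to the channel standard deviation", {
  t <- (0:99999) / 4000
  s <- sqrt(2) * sin(2 * pi * 130 * t)  # unit-variance sinusoid
  x <- cbind(s, s)
  expect_identical(add_noise(x, 0), x)
  set.seed(31)
  out <- add_noise(x, 0.075)
  for (j in 1:2) {
    noise_sd <- sd(out[, j] - x[, j])
    expect_equal(noise_sd, 0.075 * sd(s), tolerance = 0.02)
  }
  # trajectory_pair input keeps its shape
  tr <- trajectory_pair(s[1:400], s[1:400])
  expect_s3_class(add_noise(tr, 0.075), "trajectory_pair")
})

test_that("the quadratic envelope interpolant passes exactly through its anchors", {
  set.seed(41)
  for (rep in 1:20) {
    n_anchor <- sample(3:8, 1)
    xa <- sort(runif(n_anchor, 0, 100))
    while (any(diff(xa) < 1e-3)) xa <- sort(runif(n_anchor, 0, 100))
    ya <- rnorm(n_anchor, 1, 0.5)
    expect_equal(quad_interp(xa, ya, xa), ya, tolerance = 1e-10)
  }
  # continuity of value between segments
  xa <- c(0, 1, 2, 3, 4, 5)
  ya <- c(1, 1.5, 0.7, 1.2, 0.9, 1.1)
  xs <- seq(0, 5, by = 0.001)
  ys <- quad_interp(xa, ya, xs)
  expect_true(all(abs(diff(ys)) < 0.01))
})

test_that("a zero-spread envelope is the identity and modulation preserves shape", {
  t <- (0:399) / 4000
  x <- cbind(0.05 * sin(2 * pi * 120 * t), 0.04 * sin(2 * pi * 120 * t))
  expect_equal(apply_envelope(x, env_sd_scale = 0), x, tolerance = 1e-12)
  set.seed(51)
  out <- apply_envelope(x, env_points = 6, env_sd_scale = 5)
  expect_equal(dim(out), dim(x))
  expect_true(all(is.finite(out)))
})

test_that("cropping takes a contiguous shared-offset window and validates lengths", {
  tr <- simulate_twomass()
  w <- crop_window(tr, 50, start = 1)
  expect_equal(w[, "left"], tr$left[1:50], ignore_attr = TRUE)
  expect_equal(w[, "right"], tr$right[1:50], ignore_attr = TRUE)
  w2 <- crop_window(tr, 50, start = 351)
  expect_equal(w2[, "left"], tr$left[351:400], ignore_attr = TRUE)
  expect_error(crop_window(tr, 401), "longer")
  expect_error(crop_window(tr, 50, start = 352), "range")
  set.seed(61)
  starts <- replicate(100, attr(crop_window(tr, 50), "start"))
  expect_true(all(starts >= 1 & starts <= 351))
})

test_that("joint normalization removes offset/scale but keeps the channel ratio", {
  set.seed(71)
  w <- cbind(0.06 * sin(1:50 / 3), 0.02 * cos(1:50 / 3)) +
    matrix(rnorm(100, 0, 0.001), 50)
  nw <- normalize_window(w)
  expect_equal(mean(nw), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(nw^2)), 1, tolerance = 1e-12)
  expect_equal(normalize_window(7.3 * w + 2), nw, tolerance = 1e-9)
  expect_equal(sd(nw[, 1]) / sd(nw[, 2]), sd(w[, 1]) / sd(w[, 2]),
               tolerance = 1e-9)
  expect_error(normalize_window(matrix(1, 50, 2)), "constant")
})

test_that("dataset generation is deterministic, split-clean and replayable", {
  ds <- tiny_dataset()
  expect_equal(length(ds$y_pa), 120)
  expect_true(all(is.finite(ds$X)))
  expect_true(all(ds$y_pa > 0))
  # identical seed -> bit-identical dataset
  ds2 <- generate_dataset(generator_config(n_target = 120, seed = 404))
  expect_identical(ds, ds2)
  # no trajectory contributes to both splits
  tr_ids <- unique(ds$provenance$traj_id[ds$split == "train"])
  va_ids <- unique(ds$provenance$traj_id[ds$split == "val"])
  expect_length(intersect(tr_ids, va_ids), 0)
  expect_equal(sum(ds$split == "train") / length(ds$split), 0.8,
               tolerance = 0.01)
  # provenance is sufficient to re-simulate a sample exactly
  for (i in c(1, 57, 120))
    expect_identical(resimulate_sample(ds, i), ds$X[i, , ] * 1)
})

test_that("an empty dataset is a valid container", {
  ds <- generate_dataset(generator_config(n_target = 0, seed = 1))
  expect_s3_class(ds, "labeled_dataset")
  expect_length(ds$y_pa, 0)
})

test_that("multiple crops per trajectory stay within one split", {
  ds <- generate_dataset(generator_config(n_target = 60, seed = 99,
                                          crops_per_trajectory = 4))
  expect_equal(length(unique(ds$provenance$traj_id)), 15)
  by_traj <- split(ds$split, ds$provenance$traj_id)
  expect_true(all(vapply(by_traj, function(s) length(unique(s)) == 1, TRUE)))
})

test_that("datasets round-trip through the text container", {
  ds <- assign_classes(tiny_dataset(), K = 7)
  dir <- tempfile("ds")
  save_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "windows.csv")))
  expect_true(file.exists(file.path(dir, "meta.json")))
  back <- load_dataset(dir)
  expect_equal(back$X, ds$X, tolerance = 1e-12)
  expect_equal(back$y_pa, ds$y_pa, tolerance = 1e-12)
  expect_identical(as.integer(back$class), as.integer(ds$class))
  expect_identical(back$split, ds$split)
  expect_equal(back$binning$bounds, ds$binning$bounds, tolerance = 1e-9)
  expect_equal(back$config$seed, ds$config$seed)
})

test_that("class assignment uses training-split label moments", {
  ds <- assign_classes(tiny_dataset(), K = 7)
  tr <- ds$y_pa[ds$split == "train"]
  expect_equal(ds$binning$mu, mean(tr))
  expect_equal(ds$binning$sigma, sd(tr))
  expect_identical(ds$class, pressure_to_class(ds$y_pa, ds$binning))
})
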