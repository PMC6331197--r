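test_that("symmetric configurations yield bitwise-identical left/right trajectories", {
  for (q in list(scaling_vector(),
                 scaling_vector(2.5, 2.5, 0.7, 0.7, 1.8, 3),
                 scaling_vector(0.5, 0.5, 1.5, 1.5, 2.2, -1))) {
    tr <- simulate_twomass(q)
    expect_identical(tr$left, tr$right)
  }
})

test_that("output length and sampling rate match the settings", {
  st <- simulation_settings(fs = 4000, n_samples = 123)
  tr <- simulate_twomass(settings = st)
  expect_length(tr$left, 123)
  expect_length(tr$right, 123)
  expect_equal(tr$fs, 4000)
})

test_that("reference configuration phonates at the fine-step reference frequency", {
  # 0.5 s recording -> 2 Hz periodogram resolution
  st <- simulation_settings(n_samples = 2000)
  tr <- simulate_twomass(settings = st)
  expect_true(as.logical(is_oscillatory(tr)))
  # independent reference: same dynamics integrated 10x finer
  st_fine <- simulation_settings(n_samples = 2000,
                                 oversample = st$oversample * 10L)
  ref <- simulate_twomass(settings = st_fine)
  expect_lte(abs(dominant_frequency(tr) - dominant_frequency(ref)), 2)
})

test_that("without driving pressure the oscillation decays and energy never increases", {
  q <- scaling_vector(QPs = 0)
  tr <- simulate_twomass(q, settings = simulation_settings(transient_ms = 0),
                         return_state = TRUE)
  # envelope decay: block-wise amplitude is non-increasing
  blocks <- split(tr$left, rep(1:8, each = 50))
  amps <- vapply(blocks, function(b) max(abs(b)), 0)
  expect_true(all(diff(amps) <= 0))
  # after the standard onset transient the motion has fully died away
  expect_false(as.logical(is_oscillatory(simulate_twomass(q))))
  E <- mechanical_energy(tr, q)
  expect_true(all(diff(E) <= 1e-12 * max(E)))
})

test_that("collision force is zero whenever the corresponding plane is open", {
  q <- scaling_vector(1.3, 0.8, 1.1, 0.9, 2, 4)
  tr <- simulate_twomass(q, return_state = TRUE)
  st <- attr(tr, "state")
  p <- model_parameters()
  a1 <- p$a01 + p$L * (st[, 1] + st[, 3])
  a2 <- p$a02 + p$L * (st[, 2] + st[, 4])
  # at least some collisions should occur in this configuration
  expect_true(any(a1 < 0) || any(a2 < 0))
  for (i in seq(1, nrow(st), by = 7)) {
    f <- twomass_forces(q, p, st[i, ])
    if (a1[i] > 0) expect_identical(unname(f[c("l1", "r1"), "collision"]), c(0, 0))
    if (a2[i] > 0) expect_identical(unname(f[c("l2", "r2"), "collision"]), c(0, 0))
    if (a1[i] < 0) expect_gt(f["l1", "collision"], 0)
  }
})

test_that("halving the integration step moves the trajectory by less than 1e-4 cm RMS", {
  st <- simulation_settings()
  tr1 <- simulate_twomass(settings = st)
  st2 <- st
  st2$oversample <- 2L * st$oversample
  tr2 <- simulate_twomass(settings = st2)
  expect_lt(sqrt(mean((tr1$left - tr2$left)^2)), 1e-4)
  expect_lt(sqrt(mean((tr1$right - tr2$right)^2)), 1e-4)
})

test_that("numerical blow-up is flagged, not thrown", {
  # extreme stiffness + pressure with collisions disabled drives divergence;
  # scan a few hard configurations and require at least the contract to hold
  qs <- list(scaling_vector(0.3, 0.3, 4, 4, 2.5, 8),
             scaling_vector(0.3, 0.3, 4, 4, 2.5, -1),
             scaling_vector(0.3, 4, 4, 0.3, 2.5, 8))
  for (q in qs) {
    tr <- simulate_twomass(q)
    expect_true(is.logical(attr(tr, "ok")))
    if (!attr(tr, "ok")) {
      res <- is_oscillatory(tr)
      expect_false(as.logical(res))
      expect_equal(attr(res, "diagnostics")$left$reason, "unstable")
    }
  }
})

test_that("scaling vector validates its bounds", {
  expect_error(scaling_vector(Qkc = -1.5), "Qkc")
  expect_error(scaling_vector(Qm_l = -1), "positive")
  expect_silent(scaling_vector(Qkc = -1))
})

test_that("trajectory files round-trip through delimited text", {
  tr <- simulate_twomass(settings = simulation_settings(n_samples = 50))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "sample,t_ms,left_cm,right_cm")
  back <- read_trajectory(path)
  expect_equal(back$left, tr$left, tolerance = 1e-12)
  expect_equal(back$right, tr$right, tolerance = 1e-12)
  expect_equal(back$fs, tr$fs)
})
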