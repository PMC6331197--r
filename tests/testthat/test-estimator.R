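test_that("the classifier learns a linearly separable two-family toy problem", {
  fix <- sine_model()
  ds <- fix$ds
  m <- fix$model
  # oracle: the two families are separated by a wide margin in a summary
  # feature (dominant frequency of the window), so near-perfect accuracy is
  # attainable
  feats <- vapply(seq_len(dim(ds$X)[1]), function(i) {
    pg <- Mod(fft(ds$X[i, , 1] - mean(ds$X[i, , 1])))^2
    which.max(pg[2:25])
  }, 0)
  margin <- min(feats[ds$class == 2]) - max(feats[ds$class == 1])
  expect_gt(margin, 0)
  va <- which(ds$split == "val")
  pred <- predict_window(m, ds$X[va, , , drop = FALSE])
  expect_gte(mean(pred$class == ds$class[va]), 0.95)
  expect_lte(nrow(m$log), 30)
})

test_that("prediction outputs are normalized, stateless and shape-checked", {
  fix <- sine_model()
  m <- fix$model
  w <- fix$ds$X[1, , ]
  p1 <- predict_window(m, w)
  expect_equal(sum(attr(p1, "probs")), 1, tolerance = 1e-6)
  # duplicated rows give identical outputs
  p2 <- predict_window(m, list(w, w))
  expect_identical(p2$pressure_pa[1], p2$pressure_pa[2])
  expect_identical(attr(p2, "probs")[1, ], attr(p2, "probs")[2, ])
  expect_equal(p1$pressure_pa, p2$pressure_pa[1])
  expect_error(predict_window(m, w[1:10, ]), "shape")
  # decoded pressure is the midpoint of the predicted class
  expect_equal(p1$pressure_pa, class_to_pressure(p1$class, m$binning))
})

test_that("an untrained network predicts no better than chance", {
  ds <- assign_classes(make_sine_dataset(n = 100, seed = 13), K = 2)
  m0 <- train_estimator(ds, network_spec(hidden_units = 16, n_classes = 2),
                        training_config(max_epochs = 0, n_runs = 1,
                                        seed = 5))[[1]]
  expect_equal(nrow(m0$log), 0)
  va <- which(ds$split == "val")
  pred <- predict_window(m0, ds$X[va, , , drop = FALSE])
  acc <- mean(pred$class == ds$class[va])
  expect_lt(acc, 0.8)  # far from the trained >= 0.95
})

test_that("training is reproducible and logs one row per epoch", {
  ds <- assign_classes(make_sine_dataset(n = 60, seed = 17), K = 2)
  cfg <- training_config(batch_size = 12, max_epochs = 4, warmup = 4,
                         n_runs = 2, seed = 11)
  sp <- network_spec(hidden_units = 8, n_classes = 2)
  a <- train_estimator(ds, sp, cfg)
  b <- train_estimator(ds, sp, cfg)
  expect_equal(a[[1]]$log, b[[1]]$log, tolerance = 1e-12)
  expect_equal(a[[2]]$log, b[[2]]$log, tolerance = 1e-12)
  expect_equal(nrow(a[[1]]$log), 4)
  # independent runs differ (different initialization substreams)
  expect_false(isTRUE(all.equal(a[[1]]$log$train_loss, a[[2]]$log$train_loss)))
})

test_that("recording-level prediction crops, normalizes and is shift-invariant", {
  fix <- sine_model()
  m <- fix$model
  t <- (0:399) / 4000
  tr <- trajectory_pair(0.05 * sin(2 * pi * 80 * t),
                        0.05 * sin(2 * pi * 80 * t + 0.3))
  set.seed(23)
  p <- predict_recording(m, tr, n_crops = 16)
  expect_equal(nrow(p), 16)
  # fixed starts -> deterministic
  p1 <- predict_recording(m, tr, n_crops = 1, starts = 5)
  p2 <- predict_recording(m, tr, n_crops = 1, starts = 5)
  expect_identical(p1, p2)
  # constant offset of the raw trajectory does not change predictions
  tr_shift <- trajectory_pair(tr$left + 2, tr$right + 2)
  p3 <- predict_recording(m, tr_shift, n_crops = 1, starts = 5)
  expect_equal(p1$pressure_pa, p3$pressure_pa)
  expect_error(predict_recording(m, trajectory_pair(1:10 / 10, 1:10 / 10)),
               "shorter")
})

test_that("models round-trip through the model directory", {
  fix <- sine_model()
  m <- fix$model
  dir <- tempfile("model")
  save_model(m, dir)
  back <- load_model(dir)
  w <- fix$ds$X[3, , ]
  expect_equal(predict_window(back, w)$pressure_pa,
               predict_window(m, w)$pressure_pa)
  expect_equal(back$log$val_loss, m$log$val_loss, tolerance = 1e-12)
  expect_equal(back$binning$bounds, m$binning$bounds, tolerance = 1e-9)
  expect_equal(back$spec$hidden_units, m$spec$hidden_units)
})

test_that("architecture and dataset contracts are enforced", {
  ds <- make_sine_dataset(n = 40, seed = 19)
  expect_error(train_estimator(ds, network_spec(n_classes = 2),
                               training_config(n_runs = 1)), "assign")
  ds <- assign_classes(ds, K = 2)
  expect_error(train_estimator(ds, network_spec(n_classes = 5),
                               training_config(n_runs = 1)), "match")
})
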