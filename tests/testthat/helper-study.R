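# The reduced study shared by the acceptance checks: 8000 windows
# (6400 train / 1600 validation), 101 balanced classes, one training run
# capped at 40 epochs — the desk-scale problem sizes discussed in the
# methods vignette. Built once per test session.

reduced_study <- function() memo("reduced_study", {
  ds <- generate_dataset(generator_config(n_target = 8000, seed = 2026))
  ds <- assign_classes(ds, K = 101)
  model <- train_estimator(
    ds, network_spec(n_classes = 101),
    training_config(max_epochs = 40, warmup = 20, n_runs = 1,
                    seed = 12026))[[1]]
  va <- which(ds$split == "val")
  pred <- predict_window(model, ds$X[va, , , drop = FALSE])
  list(ds = ds, model = model,
       report = score(pred$pressure_pa, ds$y_pa[va]),
       baseline = baseline_report(ds$y_pa[ds$split == "train"],
                                  ds$y_pa[va]))
})
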