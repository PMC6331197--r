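# Shared fixtures, built lazily and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small generated dataset shared by synthesis/estimator tests
tiny_dataset <- function() memo("tiny_dataset", {
  generate_dataset(generator_config(n_target = 120, seed = 404))
})

# two separable sinusoid families as a labeled_dataset (for estimator tests)
make_sine_dataset <- function(n = 200, freqs = c(80, 240), seed = 7,
                              labels_pa = c(600, 1400)) {
  set.seed(seed)
  X <- array(NA_real_, c(n, 50, 2))
  cls <- rep(1:2, length.out = n)
  tt <- (0:49) / 4000
  for (i in seq_len(n)) {
    f <- freqs[cls[i]] * runif(1, 0.95, 1.05)
    ph <- runif(1, 0, 2 * pi)
    s <- sin(2 * pi * f * tt + ph)
    X[i, , ] <- normalize_window(cbind(s + rnorm(50, 0, 0.05),
                                       s + rnorm(50, 0, 0.05)))
  }
  structure(list(X = X, y_pa = labels_pa[cls],
                 split = rep(c(rep("train", 4), "val"), length.out = n),
                 provenance = data.frame(traj_id = seq_len(n)),
                 config = NULL, n_rejected = 0L, n_trajectories = n,
                 class = NULL, binning = NULL),
            class = "labeled_dataset")
}

sine_model <- function() memo("sine_model", {
  ds <- assign_classes(make_sine_dataset(), K = 2)
  list(ds = ds,
       model = train_estimator(
         ds, network_spec(hidden_units = 32, n_classes = 2),
         training_config(batch_size = 20, max_epochs = 30, warmup = 30,
                         n_runs = 1, seed = 3))[[1]])
})
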