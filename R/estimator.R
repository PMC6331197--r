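#' Recurrent classifier architecture
#'
#' A single LSTM layer feeding a dense softmax head: the last time step's
#' recurrent output, after dropout, is linearly mapped to `n_classes` logits.
#'
#' @param hidden_units number of LSTM cells (default 128).
#' @param dropout_p dropout probability on the recurrent output at training
#'   time (default 0.5); always disabled at prediction time.
#' @param n_classes number of output classes (must match the binning).
#' @param input_shape `(time steps, channels)`; default 50 x 2.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(hidden_units = 128, dropout_p = 0.5,
                         n_classes = 1007, input_shape = c(50, 2)) {
  stopifnot(hidden_units >= 1, dropout_p >= 0, dropout_p < 1, n_classes >= 1,
            length(input_shape) == 2)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_p = dropout_p, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "network_spec")
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 100).
#' @param max_epochs hard epoch cap (default 400). `max_epochs = 0` returns
#'   the freshly initialized, untrained network.
#' @param patience epochs without a new best validation loss before stopping
#'   (default 5).
#' @param warmup epochs before the patience rule is armed (default 20);
#'   early stopping only applies after initial convergence.
#' @param clip_norm global gradient-norm clipping threshold (default 5).
#' @param n_runs independently initialized training repetitions whose metrics
#'   are averaged (default 10).
#' @param seed base RNG seed; run `r` uses `seed + r - 1`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr = 0.001, batch_size = 100, max_epochs = 400,
                            patience = 5, warmup = 20, clip_norm = 5,
                            n_runs = 10, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 0, patience >= 1,
            warmup >= 0, clip_norm > 0, n_runs >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), warmup = as.integer(warmup),
                 clip_norm = clip_norm, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "training_config")
}

.dataset_tensor <- function(ds, rows) {
  ds$X[rows, , , drop = FALSE]
}

#' Train the pressure classifier
#'
#' Trains `cfg$n_runs` independently initialized copies of the network on the
#' training split, minimizing softmax cross-entropy over the balanced
#' pressure classes with Adam and global-norm gradient clipping. Each epoch
#' the validation split is scored (dropout off); training stops when the
#' validation loss has not improved for `patience` epochs (armed after
#' `warmup` epochs) or at `max_epochs`. The weights at the stopping epoch are
#' returned — no best-epoch rollback. A run whose loss turns non-finite is
#' reported with status `"diverged"`; remaining runs still execute.
#'
#' @param ds a `labeled_dataset` with classes assigned
#'   (see [assign_classes()]).
#' @param spec a [network_spec()]; its `n_classes` must equal the binning's
#'   `K`.
#' @param cfg a [training_config()].
#' @param verbose print per-epoch progress.
#' @return A list of `trained_model` objects (one per run), each with
#'   `weights`, `spec`, `binning`, `log` (per-epoch data frame), `status`,
#'   `seed`.
#' @export
train_estimator <- function(ds, spec = network_spec(), cfg = training_config(),
                            verbose = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$class) || is.null(ds$binning))
    stop("assign classes first (assign_classes)")
  if (spec$n_classes != ds$binning$K)
    stop("network n_classes must match binning K")
  if (any(ds$class < 1L | ds$class > spec$n_classes))
    stop("class labels out of range")

  tr <- which(ds$split == "train")
  va <- which(ds$split == "val")
  if (!length(tr) || !length(va)) stop("dataset must carry a train/val split")

  Xtr <- .dataset_tensor(ds, tr)
  Xva <- .dataset_tensor(ds, va)
  # one scalar input scale for the whole dataset: brings displacements to
  # unit RMS for well-conditioned gate activations while preserving the
  # between-window amplitude differences that encode the pressure
  input_scale <- sqrt(mean(Xtr^2))
  if (input_scale == 0) input_scale <- 1
  Xtr <- Xtr / input_scale
  Xva <- Xva / input_scale
  ytr <- ds$class[tr] - 1L
  yva <- ds$class[va] - 1L
  mids <- class_to_pressure(seq_len(ds$binning$K), ds$binning)

  models <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    set.seed(cfg$seed + r - 1L)
    W0 <- .cpp_lstm_init(spec$input_shape[2], spec$hidden_units,
                         spec$n_classes)
    fit <- .cpp_lstm_train(Xtr, ytr, Xva, yva, mids, ds$y_pa[va], W0,
                           cfg$lr, cfg$batch_size, cfg$max_epochs,
                           cfg$patience, cfg$warmup, cfg$clip_norm,
                           spec$dropout_p)
    log <- data.frame(epoch = seq_len(fit$epochs_run),
                      train_loss = fit$train_loss, val_loss = fit$val_loss,
                      val_acc = fit$val_acc, val_mape = fit$val_mape,
                      grad_norm = fit$grad_norm, clip_frac = fit$clip_frac)
    if (verbose && nrow(log))
      message(sprintf(
        "run %d: %d epochs, val loss %.4f, val MAPE %.2f%% [%s]",
        r, nrow(log), log$val_loss[nrow(log)], log$val_mape[nrow(log)],
        fit$status))
    models[[r]] <- structure(
      list(weights = fit$weights, spec = spec, binning = ds$binning,
           log = log, status = fit$status, seed = cfg$seed + r - 1L,
           training = cfg, input_scale = input_scale,
           preprocess = if (!is.null(ds$config)) ds$config$normalize
                        else "center"),
      class = "trained_model")
  }
  models
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> LSTM(%d) -> %d classes; %d epochs [%s]\n",
              x$spec$hidden_units, x$spec$n_classes, nrow(x$log), x$status))
  if (nrow(x$log))
    cat(sprintf("  final val loss %.4f, val MAPE %.2f%%\n",
                x$log$val_loss[nrow(x$log)], x$log$val_mape[nrow(x$log)]))
  invisible(x)
}

# windows -> (n, T, C) tensor
.window_tensor <- function(w, spec) {
  if (is.matrix(w)) w <- list(w)
  n <- length(w)
  X <- array(NA_real_, c(n, spec$input_shape[1], spec$input_shape[2]))
  for (i in seq_len(n)) {
    wi <- w[[i]]
    if (!is.matrix(wi) || nrow(wi) != spec$input_shape[1] ||
        ncol(wi) != spec$input_shape[2])
      stop("window shape must be ", spec$input_shape[1], " x ",
           spec$input_shape[2])
    X[i, , ] <- wi
  }
  X
}

#' Predict pressure for normalized windows
#'
#' Runs the classifier (dropout off), takes the argmax class, and decodes it
#' to the class-midpoint pressure.
#'
#' @param model a `trained_model`.
#' @param w a single time x 2 window matrix, a list of such matrices, or an
#'   `(n, T, 2)` array.
#' @return A data frame with columns `class`, `pressure_pa` and attribute
#'   `probs` (n x K matrix of class probabilities).
#' @export
predict_window <- function(model, w) {
  stopifnot(inherits(model, "trained_model"))
  X <- if (is.array(w) && length(dim(w)) == 3) w else .window_tensor(w, model$spec)
  if (dim(X)[2] != model$spec$input_shape[1] ||
      dim(X)[3] != model$spec$input_shape[2])
    stop("window shape mismatch")
  if (!is.null(model$input_scale)) X <- X / model$input_scale
  probs <- .cpp_lstm_forward(model$weights, X)
  cls <- max.col(probs, ties.method = "first")
  out <- data.frame(class = cls,
                    pressure_pa = class_to_pressure(cls, model$binning))
  attr(out, "probs") <- probs
  out
}

#' Predict pressure for a whole recording
#'
#' Emulates the evaluation protocol for full-length recordings: crops
#' `n_crops` windows of the network's input length at random start points,
#' applies the same per-window preprocessing the model was trained with,
#' and predicts each window independently — every window counts as a
#' separate test sample.
#'
#' @param model a `trained_model`.
#' @param traj a `trajectory_pair` of at least the window length.
#' @param n_crops number of windows (default 16).
#' @param starts optional fixed 1-based start indices (length `n_crops`);
#'   drawn uniformly when `NULL`.
#' @return A data frame with one row per window: `start`, `class`,
#'   `pressure_pa`.
#' @export
predict_recording <- function(model, traj, n_crops = 16, starts = NULL) {
  wl <- model$spec$input_shape[1]
  if (length(traj$left) < wl) stop("trajectory shorter than the input window")
  if (is.null(starts))
    starts <- sample.int(length(traj$left) - wl + 1L, n_crops, replace = TRUE)
  stopifnot(length(starts) == n_crops)
  mode <- if (is.null(model$preprocess)) "center" else model$preprocess
  wins <- lapply(starts, function(s)
    preprocess_window(crop_window(traj, wl, start = s), mode))
  pred <- predict_window(model, wins)
  data.frame(start = as.integer(starts), class = pred$class,
             pressure_pa = pred$pressure_pa)
}

#' Save / load a trained model directory
#'
#' The directory holds the weights and the associated binning, architecture,
#' training configuration and per-epoch log as delimited text and JSON.
#'
#' @param model a `trained_model`.
#' @param dir output directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(model$weights))
    data.table::fwrite(data.table::as.data.table(as.matrix(model$weights[[nm]])),
                       file.path(dir, paste0("weights_", nm, ".csv")))
  data.table::fwrite(model$log, file.path(dir, "training_log.csv"))
  meta <- list(spec = unclass(model$spec),
               binning = unclass(model$binning),
               training = unclass(model$training),
               status = model$status, seed = model$seed,
               preprocess = model$preprocess,
               input_scale = model$input_scale)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nms <- c("Wx", "Wh", "b", "Wy", "by")
  weights <- lapply(nms, function(nm) {
    m <- as.matrix(data.table::fread(file.path(dir, paste0("weights_", nm, ".csv"))))
    dimnames(m) <- NULL
    if (nm %in% c("b", "by")) m else m
  })
  names(weights) <- nms
  spec <- do.call(network_spec, meta$spec)
  binning <- structure(list(bounds = meta$binning$bounds,
                            K = as.integer(meta$binning$K),
                            mu = meta$binning$mu, sigma = meta$binning$sigma),
                       class = "class_binning")
  training <- do.call(training_config, meta$training)
  structure(list(weights = weights, spec = spec, binning = binning,
                 log = as.data.frame(data.table::fread(
                   file.path(dir, "training_log.csv"))),
                 status = meta$status, seed = meta$seed, training = training,
                 preprocess = if (is.null(meta$preprocess)) "center"
                              else meta$preprocess,
                 input_scale = meta$input_scale),
            class = "trained_model")
}
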