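#' Score pressure predictions against labels
#'
#' Computes the error metrics used throughout: mean absolute percentage
#' error, mean absolute error, signed-error mean and SD, absolute-error
#' quartiles (linear interpolation between order statistics) and the
#' fraction of absolute errors below a reference threshold — by default
#' 35 Pa, the reproduction accuracy of the pressure transducer used in the
#' ex vivo experiments.
#'
#' @param preds predicted pressures (Pa).
#' @param labels true pressures (Pa), strictly positive.
#' @param threshold reference absolute-error threshold (Pa).
#' @return An object of class `eval_report`: list with `mape` (percent),
#'   `mae` (Pa), `mean_signed_error`, `sd_error`, `percentiles` (25/50/75 of
#'   the absolute error), `frac_below`, `n`.
#' @export
score <- function(preds, labels, threshold = 35) {
  if (length(preds) == 0) stop("empty input")
  if (length(preds) != length(labels)) stop("length mismatch")
  if (any(labels <= 0)) stop("labels must be strictly positive")
  err <- preds - labels
  ae <- abs(err)
  structure(list(
    mape = 100 * mean(ae / labels),
    mae = mean(ae),
    mean_signed_error = mean(err),
    sd_error = sd(err),
    percentiles = quantile(ae, c(0.25, 0.5, 0.75), names = TRUE),
    frac_below = mean(ae < threshold),
    threshold = threshold,
    n = length(preds)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n", x$n))
  cat(sprintf("  MAPE %.2f%%   MAE %.1f Pa\n", x$mape, x$mae))
  cat(sprintf("  signed error %.1f +/- %.1f Pa\n",
              x$mean_signed_error, x$sd_error))
  cat(sprintf("  |error| quartiles: %.1f / %.1f / %.1f Pa\n",
              x$percentiles[1], x$percentiles[2], x$percentiles[3]))
  cat(sprintf("  %.1f%% of |errors| below %g Pa\n",
              100 * x$frac_below, x$threshold))
  invisible(x)
}

#' Aggregate per-run reports
#'
#' Metrics are computed per training run and then averaged; standard
#' deviations are across runs.
#'
#' @param reports list of `eval_report` objects (one per run).
#' @return A list with `mean` and `sd` vectors over the scalar metrics, plus
#'   `per_run` (data frame).
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  per_run <- do.call(rbind, lapply(reports, function(r)
    data.frame(mape = r$mape, mae = r$mae,
               mean_signed_error = r$mean_signed_error, sd_error = r$sd_error,
               q25 = unname(r$percentiles[1]), q50 = unname(r$percentiles[2]),
               q75 = unname(r$percentiles[3]), frac_below = r$frac_below)))
  list(mean = colMeans(per_run),
       sd = apply(per_run, 2, sd),
       per_run = per_run)
}

#' Model-evaluation efficiency ratio
#'
#' How many times fewer forward-model evaluations the once-trained surrogate
#' needs compared with per-recording optimization
#' (`n_evals_baseline / n_evals_new`).
#'
#' @param n_evals_baseline total model evaluations of the baseline approach.
#' @param n_evals_new total model evaluations of the new approach.
#' @return The ratio.
#' @export
efficiency_ratio <- function(n_evals_baseline, n_evals_new) {
  if (n_evals_baseline <= 0 || n_evals_new <= 0)
    stop("evaluation counts must be positive")
  n_evals_baseline / n_evals_new
}

#' Mean-predictor baseline error
#'
#' The trivial estimator that predicts the training-label mean for every
#' input; any useful surrogate must beat it clearly.
#'
#' @param train_labels training pressures (Pa).
#' @param val_labels validation pressures (Pa).
#' @param threshold see [score()].
#' @return An `eval_report`.
#' @export
baseline_report <- function(train_labels, val_labels, threshold = 35) {
  score(rep(mean(train_labels), length(val_labels)), val_labels,
        threshold = threshold)
}

#' Sweep dataset sizes or class granularities
#'
#' Re-runs generate/bin/train/score over a grid of dataset sizes and/or
#' class counts, mirroring the experimental design of the dataset-size and
#' granularity studies. One row per setting.
#'
#' @param n_samples vector of dataset sizes.
#' @param K vector of class counts.
#' @param gen_cfg base [generator_config()] (its `n_target` is overridden).
#' @param spec base [network_spec()] (its `n_classes` is overridden).
#' @param train_cfg a [training_config()].
#' @param params,settings,criteria simulator configuration.
#' @param verbose print progress.
#' @return A data frame with one row per (n_samples, K) combination:
#'   final train/validation losses, validation MAPE/MAE, epochs run, and the
#'   train-validation loss gap as an overfitting indicator.
#' @export
sweep_settings <- function(n_samples, K,
                           gen_cfg = generator_config(),
                           spec = network_spec(),
                           train_cfg = training_config(),
                           params = model_parameters(),
                           settings = simulation_settings(),
                           criteria = oscillation_criteria(),
                           verbose = FALSE) {
  grid <- expand.grid(n_samples = n_samples, K = K)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    gc <- gen_cfg
    gc$n_target <- as.integer(grid$n_samples[g])
    ds <- generate_dataset(gc, params, settings, criteria)
    ds <- assign_classes(ds, K = grid$K[g])
    sp <- spec
    sp$n_classes <- as.integer(grid$K[g])
    models <- train_estimator(ds, sp, train_cfg)
    reports <- lapply(models, function(m) {
      va <- which(ds$split == "val")
      pred <- predict_window(m, .dataset_tensor(ds, va))
      score(pred$pressure_pa, ds$y_pa[va])
    })
    agg <- aggregate_runs(reports)
    logs <- lapply(models, function(m) m$log)
    last <- function(v) if (length(v)) v[length(v)] else NA_real_
    rows[[g]] <- data.frame(
      n_samples = grid$n_samples[g], K = grid$K[g],
      train_loss = mean(vapply(logs, function(l) last(l$train_loss), 0)),
      val_loss = mean(vapply(logs, function(l) last(l$val_loss), 0)),
      loss_gap = mean(vapply(logs, function(l)
        last(l$val_loss) - last(l$train_loss), 0)),
      val_mape = agg$mean[["mape"]], val_mae = agg$mean[["mae"]],
      epochs = mean(vapply(logs, nrow, 0L)))
    if (verbose) message(sprintf("n=%d K=%d: MAPE %.2f%%", grid$n_samples[g],
                                 grid$K[g], rows[[g]]$val_mape))
  }
  do.call(rbind, rows)
}
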