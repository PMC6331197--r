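#' Configuration of the synthetic-data generator
#'
#' Settings for producing labeled training windows: how many samples, over
#' which region of the configuration space, which Gaussian the pressure
#' labels follow, and the augmentation applied to make the clean simulated
#' trajectories resemble experimental high-speed-video trajectories
#' (additive measurement noise and a slow multiplicative amplitude
#' modulation).
#'
#' @param n_target number of labeled windows to produce.
#' @param bounds 2 x 6 bounds matrix, see [scaling_bounds()].
#' @param ps_mean,ps_sd mean and standard deviation (Pa) of the Gaussian the
#'   subglottal pressure labels are drawn from, truncated by rejection to the
#'   pressure-factor bounds. The mean matches the 996 Pa reported for the
#'   ex vivo recordings; their standard deviation is not published, and
#'   300 Pa is used as a realistic spread that keeps most labels inside the
#'   392--1960 Pa class range.
#' @param calibration_factor multiplicative label correction compensating the
#'   lumped model's systematic pressure underestimation relative to
#'   experiment (1.0 = no correction; see the methods vignette).
#' @param noise_scale additive Gaussian noise SD as a fraction of the
#'   channel's own SD (default 0.075).
#' @param env_points number of amplitude-envelope anchor points (default 6).
#' @param env_sd_scale anchor SD as a multiple of the channel SD; anchors are
#'   drawn from N(1, env_sd_scale * sigma).
#' @param window_len crop length fed to the estimator (default 50 samples).
#' @param crops_per_trajectory windows cut from each simulated trajectory.
#' @param normalize per-window preprocessing: `"center"` (default) subtracts
#'   the joint mean but keeps the physical displacement scale — the
#'   oscillation amplitude is strongly pressure-dependent and is the
#'   estimator's main cue; `"full"` additionally divides by the joint SD
#'   (see [normalize_window()]), for inputs whose length calibration is
#'   unknown; `"none"` leaves windows untouched.
#' @param seed RNG seed; every sample derives its own substream from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_target = 40000,
                             bounds = scaling_bounds(),
                             ps_mean = 996, ps_sd = 300,
                             calibration_factor = 1.0,
                             noise_scale = 0.075,
                             env_points = 6, env_sd_scale = 5,
                             window_len = 50,
                             crops_per_trajectory = 1,
                             normalize = c("center", "full", "none"),
                             seed = 1L) {
  stopifnot(n_target >= 0, ps_sd > 0, noise_scale >= 0, env_points >= 3,
            window_len >= 1, crops_per_trajectory >= 1)
  normalize <- match.arg(normalize)
  if (calibration_factor <= 0) stop("calibration_factor must be positive")
  structure(list(n_target = as.integer(n_target), bounds = bounds,
                 ps_mean = ps_mean, ps_sd = ps_sd,
                 calibration_factor = calibration_factor,
                 noise_scale = noise_scale, env_points = as.integer(env_points),
                 env_sd_scale = env_sd_scale, window_len = as.integer(window_len),
                 crops_per_trajectory = as.integer(crops_per_trajectory),
                 normalize = normalize,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Apply the configured per-window preprocessing
#'
#' @param w a time x 2 window matrix.
#' @param mode `"center"`, `"full"` or `"none"`.
#' @return The preprocessed window.
#' @export
preprocess_window <- function(w, mode = "center") {
  switch(mode,
         center = w - mean(w),
         full = normalize_window(w),
         none = w,
         stop("unknown preprocessing mode: ", mode))
}

#' Draw random model configurations
#'
#' Mass, stiffness and collision factors are uniform within their bounds; the
#' pressure factor is drawn as a pressure in Pa from the configured Gaussian,
#' truncated by rejection to the factor bounds, and converted via
#' 1 factor unit = 800 Pa.
#'
#' @param n number of configurations.
#' @param cfg a [generator_config()]. Uses the current RNG state; call
#'   `set.seed()` for reproducibility.
#' @return An `n` x 6 matrix, one [scaling_vector()] per row.
#' @export
sample_parameters <- function(n, cfg = generator_config()) {
  b <- cfg$bounds
  nm <- colnames(b)
  out <- matrix(NA_real_, n, 6, dimnames = list(NULL, nm))
  if (n == 0) return(out)
  for (j in c("Qm_l", "Qm_r", "Qk_l", "Qk_r", "Qkc"))
    out[, j] <- runif(n, b["lower", j], b["upper", j])
  out[, "QPs"] <- .sample_qps(n, cfg)
  out
}

# truncated-Gaussian pressure factor via rejection
.sample_qps <- function(n, cfg) {
  lo <- cfg$bounds["lower", "QPs"] * 800
  hi <- cfg$bounds["upper", "QPs"] * 800
  out <- numeric(0)
  while (length(out) < n) {
    p <- rnorm(n, cfg$ps_mean, cfg$ps_sd)
    out <- c(out, p[p >= lo & p <= hi])
  }
  out[seq_len(n)] / 800
}

#' Calibrate a pressure label
#'
#' Multiplicative correction for the lumped model's tendency to underestimate
#' the subglottal pressure relative to experimental measurements.
#'
#' @param pressure_pa pressure label(s) in Pa.
#' @param factor positive calibration factor.
#' @return `factor * pressure_pa`.
#' @export
calibrate_label <- function(pressure_pa, factor) {
  if (!is.numeric(factor) || any(factor <= 0))
    stop("calibration factor must be positive")
  factor * pressure_pa
}

# coerce trajectory_pair / matrix to a time x 2 channel matrix and remember
# how to restore the input shape
.as_channels <- function(x) {
  if (inherits(x, "trajectory_pair"))
    list(m = cbind(left = x$left, right = x$right), traj = x)
  else if (is.matrix(x) && ncol(x) == 2) list(m = x, traj = NULL)
  else stop("expected a trajectory_pair or a time x 2 matrix")
}

.restore <- function(m, shape) {
  if (is.null(shape$traj)) return(m)
  out <- shape$traj
  out$left <- m[, 1]
  out$right <- m[, 2]
  out
}

#' Add trajectory-relative measurement noise
#'
#' Adds i.i.d. Gaussian noise to each channel with standard deviation
#' `noise_scale` times that channel's own standard deviation, emulating
#' recording and segmentation noise in experimental trajectories. Noise is
#' drawn independently per channel.
#'
#' @param x a `trajectory_pair` or a time x 2 matrix.
#' @param noise_scale noise SD as a fraction of the channel SD.
#' @return Same shape as the input.
#' @export
add_noise <- function(x, noise_scale = 0.075) {
  sh <- .as_channels(x)
  m <- sh$m
  if (noise_scale > 0) {
    for (j in 1:2) m[, j] <- m[, j] + rnorm(nrow(m), 0, noise_scale * sd(m[, j]))
  }
  .restore(m, sh)
}

#' Quadratic-spline interpolation through anchor points
#'
#' Piecewise-quadratic interpolant passing exactly through the anchors, with
#' continuous first derivative; the first segment's initial slope is the
#' secant of the first two anchors.
#'
#' @param x_anchor,y_anchor anchor abscissae (strictly increasing) and values.
#' @param x_out evaluation points within the anchor range.
#' @return Interpolant values at `x_out`.
#' @export
quad_interp <- function(x_anchor, y_anchor, x_out) {
  n <- length(x_anchor)
  stopifnot(n >= 2, length(y_anchor) == n, all(diff(x_anchor) > 0))
  h <- diff(x_anchor)
  slope <- diff(y_anchor) / h
  z <- numeric(n)
  z[1] <- slope[1]
  for (i in 1:(n - 1)) z[i + 1] <- 2 * slope[i] - z[i]
  seg <- pmin(pmax(findInterval(x_out, x_anchor), 1L), n - 1L)
  dx <- x_out - x_anchor[seg]
  y_anchor[seg] + z[seg] * dx + (z[seg + 1] - z[seg]) / (2 * h[seg]) * dx^2
}

#' Apply a slow amplitude-modulation envelope
#'
#' Emulates the cycle-to-cycle amplitude variation of real vocal-fold
#' oscillation: per channel, `env_points` anchor values are drawn from
#' N(1, `env_sd_scale` * sigma) — sigma being that channel's standard
#' deviation — at equally spaced times spanning the signal (endpoints
#' included), a quadratic spline is passed through them, clipped at zero
#' (a negative amplitude gain is physically meaningless), and the signal is
#' multiplied pointwise by the result.
#'
#' @param x a `trajectory_pair` or a time x 2 matrix.
#' @param env_points number of anchors (>= 3).
#' @param env_sd_scale anchor SD as a multiple of the channel SD.
#' @return Same shape as the input.
#' @export
apply_envelope <- function(x, env_points = 6, env_sd_scale = 5) {
  stopifnot(env_points >= 3)
  sh <- .as_channels(x)
  m <- sh$m
  n <- nrow(m)
  t_anchor <- seq(1, n, length.out = env_points)
  for (j in 1:2) {
    anchors <- rnorm(env_points, 1, env_sd_scale * sd(m[, j]))
    env <- pmax(quad_interp(t_anchor, anchors, seq_len(n)), 0)
    m[, j] <- m[, j] * env
  }
  .restore(m, sh)
}

#' Crop a fixed-length window from a trajectory pair
#'
#' @param traj a `trajectory_pair`.
#' @param window_len window length in samples.
#' @param start 1-based start index; if `NULL`, drawn uniformly.
#' @return A `window_len` x 2 matrix (columns `left`, `right`) with attribute
#'   `start`.
#' @export
crop_window <- function(traj, window_len = 50, start = NULL) {
  n <- length(traj$left)
  if (window_len > n) stop("window longer than trajectory")
  if (is.null(start)) start <- sample.int(n - window_len + 1L, 1L)
  if (start < 1 || start > n - window_len + 1) stop("start out of range")
  idx <- start:(start + window_len - 1L)
  structure(cbind(left = traj$left[idx], right = traj$right[idx]),
            start = as.integer(start))
}

#' Jointly normalize a window
#'
#' Subtracts the mean and divides by the standard deviation computed jointly
#' over both channels, removing the absolute displacement scale (unknown for
#' video-derived trajectories) while preserving the left/right amplitude
#' ratio.
#'
#' @param w a time x 2 window matrix.
#' @return The normalized window.
#' @export
normalize_window <- function(w) {
  mu <- mean(w)
  s <- sqrt(mean((w - mu)^2))
  if (s == 0) stop("constant window cannot be normalized")
  (w - mu) / s
}

# everything done to one accepted/attempted trajectory under its own
# substream; returns NULL if the configuration is rejected
.generate_one <- function(sub_seed, cfg, params, settings, criteria) {
  set.seed(sub_seed)
  q <- drop(sample_parameters(1, cfg))
  traj <- simulate_twomass(scaling_vector(q[1], q[2], q[3], q[4], q[5], q[6]),
                           params, settings)
  if (!isTRUE(as.logical(is_oscillatory(traj, criteria)))) return(NULL)
  label_raw <- q[["QPs"]] * 800
  aug <- add_noise(traj, cfg$noise_scale)
  aug <- apply_envelope(aug, cfg$env_points, cfg$env_sd_scale)
  windows <- vector("list", cfg$crops_per_trajectory)
  starts <- integer(cfg$crops_per_trajectory)
  for (ci in seq_len(cfg$crops_per_trajectory)) {
    w <- crop_window(aug, cfg$window_len)
    starts[ci] <- attr(w, "start")
    windows[[ci]] <- preprocess_window(w, cfg$normalize)
  }
  list(q = q, label_raw = label_raw, windows = windows, starts = starts)
}

#' Generate a labeled synthetic dataset
#'
#' Repeats \{draw a configuration, simulate, keep only sustained oscillation,
#' calibrate the pressure label, add noise and amplitude modulation, crop and
#' normalize\} until the target number of windows is collected, then assigns
#' an 8:2 train/validation split over *trajectories* so no simulated
#' trajectory contributes windows to both splits. Fully deterministic given
#' `cfg$seed`: each attempted trajectory runs under its own sub-seed recorded
#' in the provenance table.
#'
#' @param cfg a [generator_config()].
#' @param params a [model_parameters()].
#' @param settings a [simulation_settings()].
#' @param criteria an [oscillation_criteria()].
#' @param split_frac fraction of trajectories assigned to training.
#' @param probe attempts used to estimate the rejection rate before
#'   committing to the full run.
#' @param verbose print progress.
#' @return An object of class `labeled_dataset`: list with `X` (n x
#'   window_len x 2 array), `y_pa`, `split` (character), `provenance`
#'   (data frame), `config`, `n_rejected`; `class`/`binning` are filled by
#'   [assign_classes()].
#' @export
generate_dataset <- function(cfg = generator_config(),
                             params = model_parameters(),
                             settings = simulation_settings(),
                             criteria = oscillation_criteria(),
                             split_frac = 0.8, probe = 100,
                             verbose = FALSE) {
  n_traj_needed <- ceiling(cfg$n_target / cfg$crops_per_trajectory)
  X <- array(NA_real_, c(cfg$n_target, cfg$window_len, 2))
  y_raw <- numeric(cfg$n_target)
  prov <- vector("list", cfg$n_target)
  n_win <- 0L
  n_acc <- 0L
  attempt <- 0L
  n_rej <- 0L

  while (n_acc < n_traj_needed) {
    attempt <- attempt + 1L
    # sub-seed per attempt: deterministic, collision-free within a run,
    # and < 2^31
    sub_seed <- (cfg$seed %% 1000003L) * 2000L + attempt
    res <- .generate_one(sub_seed, cfg, params, settings, criteria)
    if (is.null(res)) {
      n_rej <- n_rej + 1L
      if (attempt == probe && n_rej / attempt > 0.95)
        stop("parameter space misconfigured: rejection rate ",
             round(100 * n_rej / attempt), "% over probe batch")
      next
    }
    n_acc <- n_acc + 1L
    for (ci in seq_along(res$windows)) {
      if (n_win >= cfg$n_target) break
      n_win <- n_win + 1L
      X[n_win, , ] <- res$windows[[ci]]
      y_raw[n_win] <- res$label_raw
      prov[[n_win]] <- data.frame(traj_id = n_acc, sub_seed = sub_seed,
                                  crop = ci, crop_start = res$starts[ci],
                                  t(res$q))
    }
    if (verbose && n_acc %% 500 == 0)
      message(sprintf("accepted %d/%d trajectories (%d rejected)",
                      n_acc, n_traj_needed, n_rej))
  }

  prov <- if (n_win > 0) do.call(rbind, prov[seq_len(n_win)]) else
    data.frame()
  y_pa <- calibrate_label(y_raw, cfg$calibration_factor)

  # 8:2 split over trajectories, reproducibly derived from the seed
  split <- character(n_win)
  if (n_acc > 0) {
    set.seed(cfg$seed %% 1000003L * 2000L)  # split substream
    traj_ids <- seq_len(n_acc)
    n_train <- round(split_frac * n_acc)
    train_ids <- sample(traj_ids, n_train)
    split <- ifelse(prov$traj_id %in% train_ids, "train", "val")
  }

  structure(list(X = X, y_pa = y_pa, split = split, provenance = prov,
                 config = cfg, n_rejected = n_rej, n_trajectories = n_acc,
                 class = NULL, binning = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(paste0("<labeled_dataset> %d windows (%d x %d) from %d ",
                     "trajectories; %d rejected\n"),
              length(x$y_pa), dim(x$X)[2], dim(x$X)[3],
              x$n_trajectories, x$n_rejected))
  if (length(x$split))
    cat(sprintf("  split: %d train / %d val\n",
                sum(x$split == "train"), sum(x$split == "val")))
  if (!is.null(x$binning))
    cat(sprintf("  classes: K = %d\n", x$binning$K))
  invisible(x)
}

#' Assign balanced class indices to a dataset
#'
#' Builds (or applies) a Gaussian-balanced [build_binning()] and fills the
#' dataset's `class` field. When a binning is built, its Gaussian moments are
#' the sample mean and SD of the *training-split* labels.
#'
#' @param ds a `labeled_dataset`.
#' @param K number of classes (ignored when `binning` is given).
#' @param binning optional pre-built `class_binning`.
#' @param lo,hi outer class bounds (Pa).
#' @return The dataset with `class` and `binning` filled.
#' @export
assign_classes <- function(ds, K = 1007, binning = NULL,
                           lo = 392, hi = 1960) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(binning)) {
    tr <- ds$y_pa[ds$split == "train"]
    if (!length(tr)) tr <- ds$y_pa
    binning <- build_binning(K, mean(tr), sd(tr), lo = lo, hi = hi)
  }
  ds$class <- pressure_to_class(ds$y_pa, binning)
  ds$binning <- binning
  ds
}

#' Re-simulate one dataset sample from its provenance
#'
#' Replays the recorded sub-seed: re-draws the configuration, re-simulates,
#' re-augments and re-crops, returning the window exactly as stored.
#'
#' @param ds a `labeled_dataset`.
#' @param i sample index.
#' @param params,settings,criteria the objects used at generation time.
#' @return The reconstructed normalized window (window_len x 2 matrix).
#' @export
resimulate_sample <- function(ds, i, params = model_parameters(),
                              settings = simulation_settings(),
                              criteria = oscillation_criteria()) {
  p <- ds$provenance[i, ]
  res <- .generate_one(p$sub_seed, ds$config, params, settings, criteria)
  if (is.null(res)) stop("provenance replay rejected the configuration")
  w <- res$windows[[p$crop]]
  attributes(w) <- list(dim = dim(w))
  w
}

#' Persist / load a labeled dataset as delimited text plus JSON
#'
#' Writes a directory with `windows.csv` (one row per sample: flattened
#' left then right channel), `samples.csv` (label, split, class, provenance)
#' and `meta.json` (generator configuration, binning, counts).
#'
#' @param ds a `labeled_dataset`.
#' @param dir output directory (created if missing).
#' @return `save_dataset` returns `dir` invisibly; `load_dataset` the
#'   reconstructed `labeled_dataset`.
#' @export
save_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ds$y_pa)
  wl <- dim(ds$X)[2]
  flat <- cbind(matrix(ds$X[, , 1], n, wl), matrix(ds$X[, , 2], n, wl))
  colnames(flat) <- c(paste0("l", seq_len(wl)), paste0("r", seq_len(wl)))
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "windows.csv"))
  samples <- data.frame(y_pa = ds$y_pa, split = ds$split,
                        class = if (is.null(ds$class)) NA_integer_ else ds$class)
  data.table::fwrite(cbind(samples, ds$provenance),
                     file.path(dir, "samples.csv"))
  meta <- list(config = unclass(ds$config),
               n_rejected = ds$n_rejected,
               n_trajectories = ds$n_trajectories,
               binning = if (is.null(ds$binning)) NULL else unclass(ds$binning))
  meta$config$bounds <- as.data.frame(ds$config$bounds)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(file.path(dir, "windows.csv")))
  samples <- as.data.frame(data.table::fread(file.path(dir, "samples.csv")))
  n <- nrow(flat)
  wl <- ncol(flat) / 2
  X <- array(NA_real_, c(n, wl, 2))
  X[, , 1] <- flat[, seq_len(wl)]
  X[, , 2] <- flat[, wl + seq_len(wl)]
  cfg <- meta$config
  b <- as.matrix(cfg$bounds)
  rownames(b) <- c("lower", "upper")
  cfg$bounds <- b
  cfg <- do.call(generator_config,
                 cfg[setdiff(names(cfg), character(0))])
  binning <- NULL
  if (!is.null(meta$binning))
    binning <- structure(list(bounds = meta$binning$bounds,
                              K = as.integer(meta$binning$K),
                              mu = meta$binning$mu, sigma = meta$binning$sigma),
                         class = "class_binning")
  cls <- samples$class
  if (all(is.na(cls))) cls <- NULL
  structure(list(X = X, y_pa = samples$y_pa, split = samples$split,
                 provenance = samples[, setdiff(names(samples),
                                                c("y_pa", "split", "class"))],
                 config = cfg, n_rejected = meta$n_rejected,
                 n_trajectories = meta$n_trajectories,
                 class = cls, binning = binning),
            class = "labeled_dataset")
}
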