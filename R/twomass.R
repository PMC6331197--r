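#' Physical constants of the reference two-mass vocal-fold model
#'
#' The symmetric reference configuration of the lumped two-mass model in the
#' (g, cm, ms) unit system, following the classic simplified parameterization:
#' each vocal fold is a lower and an upper mass anchored by springs and
#' dampers, coupled vertically, with a piecewise-linear collision spring that
#' engages when a glottal plane closes, and a Bernoulli driving pressure
#' acting on the lower masses. In this unit system a pressure of 0.008
#' corresponds to 800 Pa.
#'
#' @param m1,m2 lower/upper mass per side-plane (g).
#' @param k1,k2 anchor spring stiffness (g/ms^2).
#' @param kc vertical coupling stiffness between the two masses of one side
#'   (g/ms^2).
#' @param r1,r2 damping coefficients (g/ms).
#' @param c_factor collision stiffness as a multiple of the anchor stiffness
#'   (dimensionless; the collision spring of mass \eqn{i} is
#'   `c_factor * k_i` before scaling).
#' @param a01,a02 rest glottal areas of the lower/upper plane (cm^2).
#' @param d1,d2 plate thicknesses (cm).
#' @param L vocal-fold length (cm).
#' @param Ps_ref reference subglottal pressure (g cm^-1 ms^-2; 0.008 = 800 Pa).
#' @return An object of class `model_parameters` (named list).
#' @export
model_parameters <- function(m1 = 0.125, m2 = 0.025,
                             k1 = 0.08, k2 = 0.008, kc = 0.025,
                             r1 = 0.02, r2 = 0.02, c_factor = 3,
                             a01 = 0.05, a02 = 0.05,
                             d1 = 0.25, d2 = 0.05, L = 1.4,
                             Ps_ref = 0.008) {
  p <- list(m1 = m1, m2 = m2, k1 = k1, k2 = k2, kc = kc, r1 = r1, r2 = r2,
            c_factor = c_factor, a01 = a01, a02 = a02, d1 = d1, d2 = d2,
            L = L, Ps_ref = Ps_ref)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model parameters must be finite and strictly positive")
  structure(p, class = "model_parameters")
}

#' Dimensionless configuration of one simulated larynx
#'
#' The six scaling factors applied to the reference model: per-side mass and
#' stiffness multipliers, a subglottal pressure multiplier, and an additive
#' collision-strength offset. The effective quantities are
#' `m_{s,i} = Qm_s * m_i`, `k_{s,i} = Qk_s * k_i`, `Ps = QPs * Ps_ref` and
#' collision stiffness `c_{s,i} = (1 + Qkc) * c_factor * k_{s,i}`, so
#' `Qkc = -1` switches collisions off entirely.
#'
#' @param Qm_l,Qm_r mass factors, left/right.
#' @param Qk_l,Qk_r stiffness factors, left/right.
#' @param QPs pressure factor.
#' @param Qkc collision-strength offset; must be >= -1.
#' @return An object of class `scaling_vector` (named numeric of length 6).
#' @export
scaling_vector <- function(Qm_l = 1, Qm_r = 1, Qk_l = 1, Qk_r = 1,
                           QPs = 1, Qkc = 0) {
  q <- c(Qm_l = unname(Qm_l), Qm_r = unname(Qm_r), Qk_l = unname(Qk_l),
         Qk_r = unname(Qk_r), QPs = unname(QPs), Qkc = unname(Qkc))
  if (any(!is.finite(q))) stop("scaling factors must be finite")
  if (any(q[1:4] <= 0)) stop("mass and stiffness factors must be positive")
  if (q[["QPs"]] < 0) stop("QPs must be non-negative")
  if (q[["Qkc"]] < -1) stop("Qkc must be >= -1 (non-negative collision stiffness)")
  structure(q, class = "scaling_vector")
}

#' Sampling-bounds of the configuration space
#'
#' Default sampling intervals for each scaling factor: mass and stiffness
#' factors uniform on \[0.3, 4.0\], pressure factor on \[0.5, 2.5\]
#' (i.e. 400--2000 Pa), collision offset on \[-1.0, 8.0\].
#'
#' @return A 2 x 6 matrix of lower/upper bounds with factor names as columns.
#' @export
scaling_bounds <- function() {
  rbind(lower = c(Qm_l = 0.3, Qm_r = 0.3, Qk_l = 0.3, Qk_r = 0.3,
                  QPs = 0.5, Qkc = -1.0),
        upper = c(Qm_l = 4.0, Qm_r = 4.0, Qk_l = 4.0, Qk_r = 4.0,
                  QPs = 2.5, Qkc = 8.0))
}

#' Simulation output settings
#'
#' @param fs output sampling rate (Hz).
#' @param n_samples number of recorded samples (400 at 4000 Hz = 100 ms).
#' @param transient_ms onset transient discarded before recording starts (ms).
#' @param oversample integration substeps per output sample (fixed-step RK4
#'   with `dt = 1000 / (fs * oversample)` ms).
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(fs = 4000, n_samples = 400,
                                transient_ms = 500, oversample = 20) {
  stopifnot(fs > 0, n_samples >= 1, transient_ms >= 0, oversample >= 1)
  structure(list(fs = fs, n_samples = n_samples, transient_ms = transient_ms,
                 oversample = as.integer(oversample)),
            class = "simulation_settings")
}

#' Construct a trajectory pair
#'
#' Container for the lateral displacement of the left and right lower-mass
#' vocal-fold edge over time.
#'
#' @param left,right numeric vectors of equal length, displacement in cm.
#' @param fs sampling rate (Hz).
#' @return An object of class `trajectory_pair`.
#' @export
trajectory_pair <- function(left, right, fs = 4000) {
  if (length(left) != length(right))
    stop("left and right trajectories must have equal length")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 fs = fs), class = "trajectory_pair")
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat(sprintf("<trajectory_pair> %d samples @ %g Hz (%.1f ms)\n",
              length(x$left), x$fs, 1000 * length(x$left) / x$fs))
  invisible(x)
}

#' @export
length.trajectory_pair <- function(x) length(x$left)

#' Simulate the two-mass model
#'
#' Integrates the four coupled oscillators (left/right x lower/upper mass)
#' with classical fixed-step 4th-order Runge-Kutta, discards the onset
#' transient, and records the lateral displacement of the two lower masses
#' at the output rate. Each mass obeys
#' \deqn{m \ddot x = F^a + F^v + F^c + F^d}
#' with a linear anchor spring plus damping, a linear vertical coupling
#' spring, a collision spring active only while the corresponding glottal
#' area \eqn{a_i = a_{0i} + L (x_{l,i} + x_{r,i})} is negative, and a
#' Bernoulli driving force on the lower masses that vanishes when the lower
#' plane is closed.
#'
#' Numerical blow-up (non-finite state or displacements beyond 100 cm) does
#' not raise an error; the returned trajectory carries `ok = FALSE` so that
#' batch generation can simply discard the configuration.
#'
#' @param q a [scaling_vector()].
#' @param params a [model_parameters()].
#' @param settings a [simulation_settings()].
#' @param init_x initial displacements (cm) of (left lower, left upper,
#'   right lower, right upper); velocities start at zero.
#' @param return_state if `TRUE`, also return the full 8-column state matrix
#'   (positions then velocities) at each output sample, for diagnostics such
#'   as energy accounting.
#' @return A `trajectory_pair` with attributes `ok` (logical) and, if
#'   requested, `state`.
#' @export
simulate_twomass <- function(q = scaling_vector(),
                             params = model_parameters(),
                             settings = simulation_settings(),
                             init_x = c(0.01, 0.01, 0.01, 0.01),
                             return_state = FALSE) {
  stopifnot(inherits(settings, "simulation_settings"))
  res <- .cpp_simulate_twomass(as.numeric(q), unclass(params),
                               settings$fs, settings$n_samples,
                               settings$transient_ms, settings$oversample,
                               as.numeric(init_x), return_state)
  out <- trajectory_pair(res$left, res$right, fs = settings$fs)
  attr(out, "ok") <- res$ok
  attr(out, "q") <- as.numeric(q)
  if (return_state) attr(out, "state") <- res$state
  out
}

#' Instantaneous force decomposition
#'
#' Evaluates the four force terms (anchor+damping, vertical coupling,
#' collision, driving) acting on each of the four masses for a given state.
#' Mainly a diagnostic: e.g. the collision column is identically zero
#' whenever the corresponding glottal plane is open.
#'
#' @param q a [scaling_vector()].
#' @param params a [model_parameters()].
#' @param state numeric of length 8: positions (l1, l2, r1, r2) then
#'   velocities, in cm and cm/ms.
#' @return A 4 x 4 matrix, rows = masses (l1, l2, r1, r2), columns =
#'   `anchor`, `coupling`, `collision`, `driving`.
#' @export
twomass_forces <- function(q, params = model_parameters(), state) {
  stopifnot(length(state) == 8)
  f <- .cpp_twomass_forces(as.numeric(q), unclass(params), as.numeric(state))
  dimnames(f) <- list(c("l1", "l2", "r1", "r2"),
                      c("anchor", "coupling", "collision", "driving"))
  f
}

#' Total mechanical energy along a simulated trajectory
#'
#' Kinetic plus potential energy (anchor springs, vertical coupling, and the
#' collision springs while engaged) per output sample, computed from the
#' recorded state. Exact for left/right-symmetric configurations; with
#' asymmetric collision stiffness the collision term uses the per-side mean.
#' With zero driving pressure the only non-conservative forces are the
#' dampers, so energy must be non-increasing.
#'
#' @param traj a trajectory from [simulate_twomass()] run with
#'   `return_state = TRUE`.
#' @param q,params the configuration used for the simulation.
#' @return Numeric vector of energies (g cm^2 / ms^2), one per output sample.
#' @export
mechanical_energy <- function(traj, q, params = model_parameters()) {
  st <- attr(traj, "state")
  if (is.null(st)) stop("simulate with return_state = TRUE first")
  q <- as.numeric(q)
  m <- c(q[1] * params$m1, q[1] * params$m2, q[2] * params$m1, q[2] * params$m2)
  k <- c(q[3] * params$k1, q[3] * params$k2, q[4] * params$k1, q[4] * params$k2)
  cc <- (1 + q[6]) * params$c_factor * k
  L <- params$L
  x <- st[, 1:4, drop = FALSE]
  v <- st[, 5:8, drop = FALSE]
  a1 <- params$a01 + L * (x[, 1] + x[, 3])
  a2 <- params$a02 + L * (x[, 2] + x[, 4])
  kin <- 0.5 * (v^2 %*% m)[, 1]
  pot <- 0.5 * (x^2 %*% k)[, 1] +
    0.5 * params$kc * ((x[, 1] - x[, 2])^2 + (x[, 3] - x[, 4])^2)
  coll <- ifelse(a1 < 0, mean(cc[c(1, 3)]) * a1^2 / (4 * L^2), 0) +
    ifelse(a2 < 0, mean(cc[c(2, 4)]) * a2^2 / (4 * L^2), 0)
  kin + pot + coll
}

#' Write / read a trajectory pair as delimited text
#'
#' Plain-text format with a header row and columns
#' `sample,t_ms,left_cm,right_cm`, one row per output sample.
#'
#' @param traj a `trajectory_pair`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory_pair`.
#' @export
write_trajectory <- function(traj, path) {
  n <- length(traj$left)
  df <- data.frame(sample = seq_len(n) - 1L,
                   t_ms = (seq_len(n) - 1L) * 1000 / traj$fs,
                   left_cm = traj$left, right_cm = traj$right)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  need <- c("sample", "t_ms", "left_cm", "right_cm")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  fs <- if (nrow(df) > 1) 1000 / (df$t_ms[2] - df$t_ms[1]) else 4000
  trajectory_pair(df$left_cm, df$right_cm, fs = round(fs, 6))
}
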