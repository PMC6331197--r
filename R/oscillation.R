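#' Criteria for sustained oscillation
#'
#' Thresholds used to decide whether a simulated trajectory shows the
#' sustained, periodic vibration characteristic of phonation. A channel
#' passes when (a) its standard deviation exceeds `amp_floor`, (b) its
#' dominant spectral peak lies within `freq_band`, and (c) that peak (with
#' `peak_halfwidth` neighbouring bins on each side, to absorb leakage)
#' carries at least `min_power_frac` of the total non-DC power.
#'
#' @param amp_floor minimum displacement standard deviation (cm). The default
#'   1e-3 cm is far below typical oscillation amplitudes (~0.05 cm) but above
#'   the residue of a decayed, non-phonating configuration.
#' @param freq_band admissible fundamental-frequency band (Hz); the default
#'   30--500 Hz generously brackets the 70--281 Hz observed in ex vivo
#'   porcine recordings.
#' @param min_power_frac minimum fraction of non-DC periodogram power in the
#'   dominant peak.
#' @param peak_halfwidth periodogram bins on each side of the peak counted as
#'   part of it.
#' @return An object of class `oscillation_criteria`.
#' @export
oscillation_criteria <- function(amp_floor = 1e-3,
                                 freq_band = c(30, 500),
                                 min_power_frac = 0.1,
                                 peak_halfwidth = 2) {
  stopifnot(amp_floor >= 0, length(freq_band) == 2, freq_band[1] < freq_band[2],
            min_power_frac >= 0, min_power_frac <= 1, peak_halfwidth >= 0)
  structure(list(amp_floor = amp_floor, freq_band = freq_band,
                 min_power_frac = min_power_frac,
                 peak_halfwidth = as.integer(peak_halfwidth)),
            class = "oscillation_criteria")
}

# one-sided periodogram (excluding DC); returns freq (Hz) and power
.periodogram <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  nf <- floor(n / 2)
  list(freq = (1:nf) * fs / n, power = sp[2:(nf + 1)])
}

.channel_oscillatory <- function(x, fs, crit) {
  if (any(!is.finite(x)))
    return(list(pass = FALSE, reason = "unstable", sdev = NA_real_,
                peak_freq = NA_real_, power_frac = NA_real_))
  sdev <- sd(x)
  if (sdev <= crit$amp_floor)
    return(list(pass = FALSE, reason = "amplitude", sdev = sdev,
                peak_freq = NA_real_, power_frac = NA_real_))
  pg <- .periodogram(x, fs)
  i_peak <- which.max(pg$power)
  f_peak <- pg$freq[i_peak]
  idx <- max(1, i_peak - crit$peak_halfwidth):min(length(pg$power),
                                                 i_peak + crit$peak_halfwidth)
  frac <- sum(pg$power[idx]) / sum(pg$power)
  pass <- f_peak >= crit$freq_band[1] && f_peak <= crit$freq_band[2] &&
    frac >= crit$min_power_frac
  reason <- if (pass) "ok"
    else if (f_peak < crit$freq_band[1] || f_peak > crit$freq_band[2]) "band"
    else "power"
  list(pass = pass, reason = reason, sdev = sdev, peak_freq = f_peak,
       power_frac = frac)
}

#' Detect sustained oscillation
#'
#' Decides whether a (post-transient) trajectory pair represents sustained
#' phonation. Both channels must individually satisfy the amplitude,
#' frequency-band and spectral-concentration criteria; configurations that
#' went numerically unstable are always rejected.
#'
#' @param traj a `trajectory_pair` (an `ok = FALSE` attribute from the
#'   simulator forces rejection).
#' @param criteria an [oscillation_criteria()].
#' @return Logical scalar with attribute `diagnostics`: a list with one entry
#'   per channel (`sdev`, `peak_freq`, `power_frac`, `reason`).
#' @export
is_oscillatory <- function(traj, criteria = oscillation_criteria()) {
  ok_attr <- attr(traj, "ok")
  if (!is.null(ok_attr) && !ok_attr) {
    res <- FALSE
    attr(res, "diagnostics") <- list(left = list(reason = "unstable"),
                                     right = list(reason = "unstable"))
    return(res)
  }
  dl <- .channel_oscillatory(traj$left, traj$fs, criteria)
  dr <- .channel_oscillatory(traj$right, traj$fs, criteria)
  res <- dl$pass && dr$pass
  attr(res, "diagnostics") <- list(left = dl, right = dr)
  res
}

#' Dominant oscillation frequency
#'
#' Frequency (Hz) of the largest periodogram peak of the mean of the two
#' channels; a convenience for inspecting simulated fundamental frequencies.
#'
#' @param traj a `trajectory_pair`.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(traj) {
  x <- (traj$left + traj$right) / 2
  pg <- .periodogram(x, traj$fs)
  pg$freq[which.max(pg$power)]
}
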