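#' Gaussian-balanced pressure classes
#'
#' Converts the scalar pressure target into `K` ordered half-open intervals
#' `[B_i, B_{i+1})` spanning `[lo, hi)` Pa such that every interval carries
#' the same probability mass under a Gaussian with the given mean and
#' standard deviation (in practice, the sample moments of the training
#' labels). The interior bounds are Gaussian quantiles
#' \deqn{B_j = F^{-1}\!\big(F(lo) + j\,[F(hi) - F(lo)]/K\big),}
#' so classes are narrow near the mode and wide in the tails.
#'
#' @param K number of classes (>= 1).
#' @param mu,sigma Gaussian mean and standard deviation (Pa), typically the
#'   training-label sample moments.
#' @param lo,hi outer bounds (Pa); defaults 392 and 1960.
#' @return An object of class `class_binning`: list with `bounds` (length
#'   K+1), `K`, `mu`, `sigma`.
#' @export
build_binning <- function(K, mu, sigma, lo = 392, hi = 1960) {
  if (K < 1) stop("K must be >= 1")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (lo >= hi) stop("lo must be < hi")
  Flo <- pnorm(lo, mu, sigma)
  Fhi <- pnorm(hi, mu, sigma)
  bounds <- qnorm(Flo + (0:K) * (Fhi - Flo) / K, mu, sigma)
  bounds[1] <- lo
  bounds[K + 1] <- hi
  if (any(diff(bounds) <= 0)) stop("degenerate binning: bounds not increasing")
  structure(list(bounds = bounds, K = as.integer(K), mu = mu, sigma = sigma),
            class = "class_binning")
}

#' @export
print.class_binning <- function(x, ...) {
  cat(sprintf("<class_binning> K = %d over [%g, %g) Pa, N(%.1f, %.1f)\n",
              x$K, x$bounds[1], x$bounds[x$K + 1], x$mu, x$sigma))
  invisible(x)
}

#' Map pressures to class indices
#'
#' Half-open membership `B_i <= y < B_{i+1}`; labels below the lowest bound
#' clamp to class 1 and labels at or above the highest bound clamp to class
#' `K` (calibration can push a label slightly out of range).
#'
#' @param y pressures (Pa).
#' @param binning a [build_binning()] object.
#' @return Integer class indices in `1:K`.
#' @export
pressure_to_class <- function(y, binning) {
  stopifnot(inherits(binning, "class_binning"), all(is.finite(y)))
  i <- findInterval(y, binning$bounds)  # 0 below lo, K+1 at/above hi
  pmin(pmax(i, 1L), binning$K)
}

#' Decode a class index to a pressure
#'
#' Returns the interval midpoint `(B_i + B_{i+1}) / 2` — the scalar estimate
#' associated with a classified class.
#'
#' @param i class indices in `1:K`.
#' @param binning a [build_binning()] object.
#' @return Pressures (Pa).
#' @export
class_to_pressure <- function(i, binning) {
  stopifnot(inherits(binning, "class_binning"))
  i <- as.integer(i)
  if (any(i < 1L | i > binning$K)) stop("class index out of range")
  (binning$bounds[i] + binning$bounds[i + 1L]) / 2
}

#' Class widths in Pa
#'
#' @param binning a [build_binning()] object.
#' @return Numeric vector of the K interval widths.
#' @export
class_widths <- function(binning) diff(binning$bounds)
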