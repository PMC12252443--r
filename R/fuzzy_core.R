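#' Summary statistics for fuzzy partition construction
#'
#' Computes the statistics that drive the data-driven Gaussian partitioning of
#' a fermentation attribute: mean, median, sample standard deviation
#' (denominator n-1), range, the floored dispersion parameter
#' kappa = max(sd, 0.01), and the dimensionless skewness adjustment
#' delta = (mean - median) / kappa.
#'
#' @param series Numeric vector, length >= 2.
#' @return A list of class `attribute_stats` with fields `mean`, `median`,
#'   `std`, `min`, `max`, `kappa`, `delta`, `n`.
#' @export
#' @examples
#' compute_stats(c(1, 2, 3, 4, 10))
compute_stats <- function(series) {
  x <- as.numeric(series)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("insufficient data: need at least 2 finite values")
  s <- sd(x)
  kappa <- if (s < 0.01) 0.01 else s
  structure(list(
    mean = mean(x), median = median(x), std = s,
    min = min(x), max = max(x),
    kappa = kappa, delta = (mean(x) - median(x)) / kappa,
    n = length(x)
  ), class = "attribute_stats")
}

#' Gaussian membership function
#'
#' exp(-(x - c)^2 / (2 w^2)): 1 at the center, symmetric, in (0, 1].
#'
#' @param x Evaluation points (vectorised).
#' @param center Center of the bell.
#' @param width Bandwidth (> 0).
#' @return Membership degrees in \code{[0, 1]}.
#' @export
gaussmf <- function(x, center, width) {
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  exp(-(x - center)^2 / (2 * width^2))
}

#' Triangular membership function
#'
#' Piecewise-linear triangle with feet `a`, `c` and peak `b`
#' (a <= b <= c).  Degenerate feet (a == b or b == c) give one-sided ramps.
#'
#' @param x Evaluation points (vectorised).
#' @param a,b,c Foot, peak, foot; non-decreasing.
#' @return Membership degrees in \code{[0, 1]}.
#' @export
trimf <- function(x, a, b, c) {
  if (is.unsorted(c(a, b, c))) stop("trimf parameters must be non-decreasing")
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
  pmax(0, pmin(up, dn, 1))
}

#' Trapezoidal membership function
#'
#' Piecewise-linear trapezoid rising on \code{[a, b]}, flat at 1 on
#' \code{[b, c]}, falling on \code{[c, d]} (a <= b <= c <= d).
#'
#' @param x Evaluation points (vectorised).
#' @param a,b,c,d Shoulder parameters; non-decreasing.
#' @return Membership degrees in \code{[0, 1]}.
#' @export
trapmf <- function(x, a, b, c, d) {
  if (is.unsorted(c(a, b, c, d))) stop("trapmf parameters must be non-decreasing")
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (d > c) (d - x) / (d - c) else as.numeric(x <= c)
  pmax(0, pmin(up, dn, 1))
}

#' S-shaped membership function
#'
#' The standard smooth S-function: 0 below `a`, 1 above `b`, 0.5 at the
#' midpoint, built from two C1-joined quadratic splines.
#'
#' @param x Evaluation points (vectorised).
#' @param a,b Lower and upper knots, a <= b.
#' @return Membership degrees in \code{[0, 1]}.
#' @export
smf <- function(x, a, b) {
  if (a > b) stop("smf parameters must be non-decreasing")
  if (a == b) return(as.numeric(x >= a))
  m <- (a + b) / 2
  y <- numeric(length(x))
  lo <- x > a & x <= m
  hi <- x > m & x < b
  y[lo] <- 2 * ((x[lo] - a) / (b - a))^2
  y[hi] <- 1 - 2 * ((x[hi] - b) / (b - a))^2
  y[x >= b] <- 1
  y
}

#' Build a three-class Gaussian partition for an attribute
#'
#' Constructs low/medium/high Gaussian membership functions from attribute
#' statistics using the calibrated layout: centers at
#' (min + c_off_low, mean + c_off_med, max + kd * delta), shared bandwidth
#' w = sd / k, and a universe of discourse widened by the calibrated range
#' offsets (low end min + c_min with c_min = -2*min; high end max + c_max with
#' c_max = 0.2*max).  The alternative `convention = "centers_eq"` places the
#' centers at (min, median, max - delta), the formula-style layout.
#'
#' @param stats An `attribute_stats` object from [compute_stats()].
#' @param name Attribute label carried in the partition.
#' @param k Bandwidth divisor, w = sd / k (default 3).
#' @param kd Skew multiplier for the high-center offset (default 1).
#' @param c_off_low,c_off_med Additive center offsets for the low and medium
#'   classes (defaults 0).
#' @param convention `"table"` (calibrated layout, default) or `"centers_eq"`.
#' @return A list of class `gaussian_partition` with fields `attribute`,
#'   `centers` (named low/medium/high), `width`, `universe` (c(lo, hi)),
#'   and `stats`.
#' @export
build_partition <- function(stats, name = "x", k = 3, kd = 1,
                            c_off_low = 0, c_off_med = 0,
                            convention = c("table", "centers_eq")) {
  convention <- match.arg(convention)
  stopifnot(inherits(stats, "attribute_stats"), k > 0)
  lo <- stats$min
  hi <- stats$max
  if (hi == lo) {
    warning("degenerate attribute range; widening by kappa")
    lo <- lo - stats$kappa
    hi <- hi + stats$kappa
  }
  centers <- if (convention == "table") {
    c(low = lo + c_off_low,
      medium = stats$mean + c_off_med,
      high = hi + kd * stats$delta)
  } else {
    c(low = lo, medium = stats$median, high = hi - stats$delta)
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    # extreme skew can push the high center below the medium one; nudge it
    # just above so the partition stays ordered
    centers <- sort(centers) + c(0, 0, 0)
    names(centers) <- c("low", "medium", "high")
    if (centers[3] <= centers[2]) centers[3] <- centers[2] + stats$kappa
  }
  width <- stats$kappa / k
  universe <- c(lo + (-2 * lo), hi + 0.2 * hi)
  universe <- sort(universe)
  structure(list(attribute = name, centers = centers, width = width,
                 universe = universe, stats = stats),
            class = "gaussian_partition")
}

#' Evaluate all three memberships of a partition
#'
#' @param partition A `gaussian_partition`.
#' @param x Evaluation points (vectorised).
#' @return A matrix `length(x)` by 3 with columns low/medium/high.
#' @export
partition_memberships <- function(partition, x) {
  m <- vapply(partition$centers,
              function(ct) gaussmf(x, ct, partition$width),
              numeric(length(x)))
  m <- matrix(m, nrow = length(x), ncol = 3)
  colnames(m) <- names(partition$centers)
  m
}

#' Gaussian smoothing of a time series
#'
#' Discrete convolution with a Gaussian kernel of standard deviation `sigma`
#' (in samples), truncated at lag `floor(4 sigma)` and renormalised to unit
#' mass.  Boundaries are handled by nearest-value padding, so a constant
#' series is returned unchanged.
#'
#' @param series Numeric vector (non-empty).
#' @param sigma Kernel standard deviation in samples (> 0).
#' @return Smoothed series of the same length.
#' @export
gaussian_smooth <- function(series, sigma = 2) {
  y <- as.numeric(series)
  if (length(y) == 0) stop("series must be non-empty")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  r <- floor(4 * sigma)
  if (r == 0) return(y)
  kern <- dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(rep(y[1], r), y, rep(y[length(y)], r))
  out <- stats::filter(padded, kern, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + length(y))])
}
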