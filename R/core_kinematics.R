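# Kinematic and statistical primitives used by every activity metric and
# balance score: prediction-ellipse sway area, hysteresis toe-tap counting,
# outlier-damped extrema, and angle variance.

#' Area of the 95% prediction ellipse of planar samples
#'
#' Postural sway statistic for balance tasks: given paired transverse-plane
#' (x, y) centre-of-mass acceleration samples, computes the area of the
#' chi-square prediction ellipse that is expected to contain `conf` of the
#' samples under a bivariate normal model. The area is
#' \eqn{\pi \, \chi^2_{2}(conf) \, \sqrt{\det C}} where \eqn{C} is the 2x2
#' sample covariance of the points.
#'
#' @param x,y Numeric vectors of equal length (m/s^2), at least 3 samples.
#' @param conf Coverage probability of the ellipse (default 0.95).
#' @return Ellipse area in (m/s^2)^2. Zero when the sample covariance is
#'   singular (constant or collinear samples).
#' @examples
#' set.seed(1)
#' ellipse_area_95(rnorm(500), rnorm(500))
#' @seealso [ellipse_area_95_cov()] for the closed form from a covariance.
#' @export
ellipse_area_95 <- function(x, y, conf = 0.95) {
  mvh_check_numeric(x, "x")
  mvh_check_numeric(y, "y")
  if (length(x) != length(y)) {
    mvh_stop("x and y must be paired samples of equal length")
  }
  if (length(x) < 3) {
    mvh_stop("at least 3 planar samples are required for an ellipse",
             class = "mvh_degenerate_error")
  }
  ellipse_area_95_cov(stats::cov(cbind(x, y)), conf = conf)
}

#' Prediction-ellipse area from a 2x2 covariance matrix
#'
#' Closed form \eqn{\pi \, \chi^2_{2}(conf) \, \sqrt{\det \Sigma}}. Exposed
#' separately so the ellipse can be computed from a known (population)
#' covariance as well as from samples.
#'
#' @param sigma A 2x2 covariance matrix.
#' @param conf Coverage probability (default 0.95).
#' @return Area; 0 if `sigma` is singular.
#' @export
ellipse_area_95_cov <- function(sigma, conf = 0.95) {
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(2, 2)) || anyNA(sigma)) {
    mvh_stop("sigma must be a 2x2 covariance matrix without missing values")
  }
  d <- det(sigma)
  if (!is.finite(d) || d <= 0) {
    return(0)
  }
  pi * stats::qchisq(conf, df = 2) * sqrt(d)
}

#' Count toe taps from raised- and plant-foot toe heights
#'
#' A tap is one downward crossing of the raised-foot toe below the plant-foot
#' toe: the difference `d = z_raised - z_plant` must move from above
#' `+hysteresis` to below `-hysteresis` for the event to count (one count per
#' physical ground contact; the return upward does not count). The hysteresis
#' band suppresses sensor jitter around zero. The count is invariant to
#' adding a common constant to both traces.
#'
#' @param z_raised,z_plant Toe vertical positions (m), equal length, same
#'   sampling rate.
#' @param hysteresis Half-width of the dead band (m), default 0.005.
#' @return Integer tap count.
#' @export
count_toe_taps <- function(z_raised, z_plant, hysteresis = 0.005) {
  mvh_check_numeric(z_raised, "z_raised")
  mvh_check_numeric(z_plant, "z_plant")
  if (length(z_raised) != length(z_plant)) {
    mvh_stop("z_raised and z_plant must have equal length")
  }
  if (!is.numeric(hysteresis) || length(hysteresis) != 1 || hysteresis <= 0) {
    mvh_stop("hysteresis must be a single positive length in metres")
  }
  d <- z_raised - z_plant
  state <- sign(d)[abs(d) > hysteresis]  # samples outside the dead band
  if (length(state) < 2) {
    return(0L)
  }
  runs <- rle(state)$values
  sum(runs[-length(runs)] == 1 & runs[-1] == -1)
}

#' Outlier-damped extremum of a series
#'
#' Extremum taken as the median of the samples at or beyond the 90th (max) or
#' 10th (min) empirical percentile, damping the influence of isolated spikes
#' relative to the raw extremum. Percentiles use the linear-interpolation
#' definition (R's default `type = 7`); even-cardinality medians are averaged.
#'
#' @param x Numeric series, length >= 1.
#' @param which `"max"` or `"min"`.
#' @return The damped extremum; always within `range(x)` and, for `"max"`,
#'   never above the raw maximum.
#' @examples
#' robust_extremum(1:100, "max")        # 95.5
#' robust_extremum(c(0:98, 1000), "max") # 94.5, not 1000
#' @export
robust_extremum <- function(x, which = c("max", "min")) {
  which <- match.arg(which)
  if (length(x) == 0) {
    mvh_stop("cannot take the extremum of an empty series")
  }
  mvh_check_numeric(x, "x")
  if (which == "max") {
    thr <- stats::quantile(x, 0.9, names = FALSE)
    stats::median(x[x >= thr])
  } else {
    thr <- stats::quantile(x, 0.1, names = FALSE)
    stats::median(x[x <= thr])
  }
}

#' Sample variance of an angle channel
#'
#' Variance (denominator n - 1) of a joint- or trunk-angle series over a
#' window, in squared degrees. Used for the trunk-sway and elbow-steadiness
#' metrics.
#'
#' @param x Angle series (deg), length >= 2.
#' @return Variance in deg^2 (0 for a constant series).
#' @export
angle_variance <- function(x) {
  if (length(x) < 2) {
    mvh_stop("variance needs at least 2 samples")
  }
  mvh_check_numeric(x, "x")
  stats::var(x)
}

#' Maximum trunk deviation from vertical
#'
#' Outlier-damped maximum of the absolute trunk deviation angle, i.e.
#' `robust_extremum(abs(x), "max")`. The input channel encodes unsigned (or
#' signed) deviation from the vertical axis in degrees.
#'
#' @param x Trunk angle series (deg), length >= 1.
#' @return Non-negative deviation angle (deg).
#' @export
max_trunk_deviation <- function(x) {
  if (length(x) == 0) {
    mvh_stop("cannot take the trunk deviation of an empty series")
  }
  mvh_check_numeric(x, "x")
  robust_extremum(abs(x), "max")
}
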