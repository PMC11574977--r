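#' Canonicalize angles to [-pi, pi)
#'
#' All colors in the package are radian positions on an isoluminant color
#' wheel, with "red" arbitrarily anchored at 0. Any real number maps to the
#' canonical half-open interval `[-pi, pi)`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length in `[-pi, pi)`.
#' @export
#' @examples
#' canonical_angle(c(0, pi, -pi, 3 * pi / 2))
canonical_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric", call. = FALSE)
  }
  ((theta + pi) %% (2 * pi)) - pi
}

#' Signed angular distance on the circle
#'
#' Computes `mod(theta - theta0 + pi, 2*pi) - pi`, the signed shortest
#' rotation taking `theta0` to `theta`. Always in `[-pi, pi)`.
#'
#' @param theta,theta0 Numeric vectors of angles in radians (recycled).
#' @return Signed distances in radians.
#' @export
#' @examples
#' angular_distance(pi - 0.1, -pi + 0.1) # wraps to -0.2
angular_distance <- function(theta, theta0) {
  if (any(!is.finite(theta)) || any(!is.finite(theta0))) {
    stop("angles must be finite", call. = FALSE)
  }
  ((theta - theta0 + pi) %% (2 * pi)) - pi
}

#' von Mises density on the circle
#'
#' Density per radian of the von Mises distribution,
#' `exp(kappa * cos(theta - mu)) / (2 * pi * I0(kappa))`, the circular
#' analogue of the Gaussian. `kappa = 0` gives the uniform density
#' `1 / (2 * pi)`.
#'
#' @param theta Angle(s) at which to evaluate, radians.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `>= 0`.
#' @return Density values (per radian).
#' @export
von_mises_density <- function(theta, mu = 0, kappa = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0) {
    stop("`kappa` must be a single finite value >= 0", call. = FALSE)
  }
  # besselI with expon.scaled guards overflow for large kappa
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Reward function of the task
#'
#' The reward (in liquid drops) for choosing color `theta` when the hidden
#' template is `template`: a von Mises profile of concentration `kappa`
#' (2.5 in the task) scaled by `r_max` and rounded to the nearest drop.
#' Rounding at exact .5 goes away from zero.
#'
#' @param theta Chosen color(s), radians.
#' @param template Template color, radians.
#' @param kappa Concentration of the reward profile (default 2.5).
#' @param r_max Maximum reward scale in drops (non-negative integer).
#' @return Integer drops, same length as `theta`.
#' @export
#' @examples
#' reward_function(0, 0, kappa = 2.5, r_max = 6) # 4 drops at the template
reward_function <- function(theta, template, kappa = 2.5, r_max = 6) {
  if (length(r_max) != 1L || !is.finite(r_max) || r_max < 0 ||
      r_max != round(r_max)) {
    stop("`r_max` must be a non-negative integer", call. = FALSE)
  }
  round_half_away(r_max * von_mises_density(theta, template, kappa))
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Color wheel grid
#'
#' The task's stimulus space: `n_colors` evenly spaced angles starting at
#' the canonical anchor `-pi`, spacing exactly `2*pi/n_colors`.
#'
#' @param n_colors Number of colors on the wheel (default 100).
#' @return Numeric vector of `n_colors` strictly increasing angles in
#'   `[-pi, pi)`.
#' @export
color_wheel <- function(n_colors = 100L) {
  stopifnot(n_colors >= 2L)
  -pi + 2 * pi * (seq_len(n_colors) - 1L) / n_colors
}

# index (1-based) of the nearest wheel color for each angle
wheel_index <- function(theta, n_colors = 100L) {
  k <- round((canonical_angle(theta) + pi) * n_colors / (2 * pi)) %% n_colors
  as.integer(k) + 1L
}

#' Circular mean
#'
#' Mean direction of a sample of angles (resultant-vector direction).
#'
#' @param theta Angles in radians.
#' @param na.rm Drop missing values first.
#' @return Mean direction in `[-pi, pi)`; `NA` if the resultant length is 0.
#' @export
circular_mean <- function(theta, na.rm = FALSE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  s <- sum(sin(theta)); c <- sum(cos(theta))
  if (s == 0 && c == 0) return(NA_real_)
  canonical_angle(atan2(s, c))
}

#' Circular correlation
#'
#' Circular-circular correlation of two angle samples (the Fisher-Lee /
#' Jammalamadaka-SenGupta coefficient used by the standard circular
#' statistics toolboxes):
#' `sum(sin(a - mean_a) * sin(b - mean_b)) / sqrt(sum(sin^2) * sum(sin^2))`.
#'
#' @param a,b Angle vectors of equal length, radians.
#' @return Correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  sa <- sin(a - circular_mean(a))
  sb <- sin(b - circular_mean(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}
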