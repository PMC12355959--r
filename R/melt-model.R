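#' Default TPP temperature gradient
#'
#' The ten-point TMT temperature gradient used throughout the package:
#' 37.1, 40.9, 44.1, 47.1, 49.7, 53.2, 56.2, 59.1, 62.4, 67.2 degrees C.
#' The first (lowest) temperature is the reference to which every melting
#' series is normalized.
#'
#' @return Numeric vector of temperatures in degrees Celsius, strictly
#'   increasing, length 10.
#' @export
tpp_gradient <- function() {
  c(37.1, 40.9, 44.1, 47.1, 49.7, 53.2, 56.2, 59.1, 62.4, 67.2)
}

#' Validate a temperature gradient
#'
#' A valid gradient is strictly increasing, has at least 5 temperatures,
#' and its first element is the reference temperature.
#'
#' @param gradient numeric vector of temperatures (degrees C).
#' @return The gradient, invisibly, if valid; otherwise an error.
#' @export
validate_gradient <- function(gradient) {
  if (length(gradient) == 0L) {
    stop("gradient: must contain at least one temperature", call. = FALSE)
  }
  if (!is.numeric(gradient) || anyNA(gradient)) {
    stop("gradient: temperatures must be finite numbers", call. = FALSE)
  }
  if (length(gradient) < 5L) {
    stop("gradient: at least 5 temperatures are required", call. = FALSE)
  }
  if (any(diff(gradient) <= 0)) {
    stop("gradient: temperatures must be strictly increasing", call. = FALSE)
  }
  if (any(gradient <= 0)) {
    stop("gradient: temperatures must be positive (degrees C)", call. = FALSE)
  }
  invisible(gradient)
}

#' Sigmoid denaturation model
#'
#' Relative soluble abundance of a protein after heating to temperature T:
#' \deqn{f(T) = \frac{1 - plateau}{1 + e^{-(a/T - b)}} + plateau}
#' For `a > 0` the curve decreases strictly in T from 1 (low temperature)
#' towards the lower asymptote `plateau` (residual soluble fraction).
#' The exponent uses `a/T - b`: the alternative `a*T` form increases with
#' temperature and cannot describe melting.
#'
#' @param temperature temperature(s) in degrees C, > 0. Scale-sensitive:
#'   the model is parameterized for Celsius inputs.
#' @param a slope constant (degrees C scaled), > 0.
#' @param b dimensionless offset constant.
#' @param plateau lower asymptote, in `[0, 1)`.
#' @return Relative abundance(s) in `(plateau, 1)`.
#' @examples
#' melt_model(50, a = 2000, b = 40)        # exponent is 0 -> 0.5
#' melt_model(tpp_gradient(), 2000, 40, 0.1)
#' @export
melt_model <- function(temperature, a, b, plateau = 0) {
  if (any(temperature <= 0)) {
    stop("temperature must be > 0", call. = FALSE)
  }
  (1 - plateau) / (1 + exp(-(a / temperature - b))) + plateau
}

#' Melting point from sigmoid parameters (closed form)
#'
#' The melting point Tm is the temperature where the relative abundance
#' falls to half its initial value, f(Tm) = 0.5. Solving the sigmoid gives
#' \deqn{T_m = \frac{a}{b - \ln\!\big(0.5 / (0.5 - plateau)\big)}}
#' which is defined only when `plateau < 0.5` and the denominator is
#' positive (otherwise the curve never crosses 0.5 in T > 0 and `NA` is
#' returned; an undefined Tm is a value, not an error).
#'
#' @param a,b,plateau sigmoid parameters (vectorized).
#' @return Melting temperature(s) in degrees C, or `NA` where undefined.
#' @examples
#' melting_point(2000, 40)        # 50: Tm = a/b when plateau = 0
#' melting_point(2000, 40, 0.2)   # ~50.65
#' melting_point(2000, 40, 0.6)   # NA: curve never reaches 0.5
#' @export
melting_point <- function(a, b, plateau = 0) {
  n <- max(length(a), length(b), length(plateau))
  a <- rep_len(a, n); b <- rep_len(b, n); plateau <- rep_len(plateau, n)
  tm <- rep(NA_real_, n)
  ok <- is.finite(a) & is.finite(b) & is.finite(plateau) &
    a > 0 & plateau >= 0 & plateau < 0.5
  denom <- b[ok] - log(0.5 / (0.5 - plateau[ok]))
  pos <- denom > 0
  tm[which(ok)[pos]] <- a[ok][pos] / denom[pos]
  tm[!is.na(tm) & tm <= 0] <- NA_real_
  tm
}

#' Melting point by numeric root finding
#'
#' Solves f(T) = 0.5 numerically with [stats::uniroot()]. Serves as an
#' independent cross-check of the closed form in [melting_point()]; the two
#' agree to better than 1e-6 degrees C wherever Tm is defined.
#'
#' @inheritParams melting_point
#' @param interval search interval in degrees C.
#' @param tol root tolerance in degrees C.
#' @return Melting temperature in degrees C, or `NA` if the curve does not
#'   cross 0.5 inside the interval.
#' @export
melting_point_numeric <- function(a, b, plateau = 0,
                                  interval = c(1e-3, 1e6), tol = 1e-9) {
  if (!is.finite(a) || !is.finite(b) || !is.finite(plateau)) return(NA_real_)
  g <- function(T) melt_model(T, a, b, plateau) - 0.5
  lo <- g(interval[1]); hi <- g(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
  stats::uniroot(g, interval = interval, tol = tol)$root
}
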