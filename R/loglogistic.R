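#' The log-logistic distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the two-parameter log-logistic distribution with scale \eqn{\alpha}
#' and shape \eqn{\beta}, parameterized by its CDF
#' \deqn{F(x) = \frac{1}{1 + (x/\alpha)^{-\beta}}, \quad x > 0.}
#'
#' If \eqn{X} is log-logistic, \eqn{\log X} is logistic with location
#' \eqn{\log\alpha} and scale \eqn{1/\beta}. The median is \eqn{\alpha};
#' the distribution is heavy-tailed for small \eqn{\beta} (the mean is
#' finite only for \eqn{\beta > 1}). It is a standard candidate family for
#' right-skewed occupational air-concentration data alongside the
#' lognormal.
#'
#' The quantile function is closed-form:
#' \deqn{Q(p) = \alpha \left(\frac{p}{1-p}\right)^{1/\beta}.}
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of observations.
#' @param shape shape parameter \eqn{\beta > 0}.
#' @param scale scale parameter \eqn{\alpha > 0} (the median).
#' @return `dllogis` gives the density, `pllogis` the CDF, `qllogis` the
#'   quantile function and `rllogis` random deviates.
#' @examples
#' qllogis(0.5, shape = 2, scale = 0.03)    # the median equals the scale
#' qllogis(0.95, shape = 1, scale = 1)      # (0.95/0.05)^1 = 19
#' pllogis(qllogis(0.3, 2, 0.5), 2, 0.5)    # round trip
#' @name loglogistic
NULL

# Invalid parameters follow the stats convention: NaN result with a
# warning, never an error, so that optimizers probing the boundary of the
# parameter space can recover.
bad_llogis_params <- function(shape, scale) {
  bad <- any(!is.finite(shape)) || any(shape <= 0) ||
    any(!is.finite(scale)) || any(scale <= 0)
  if (bad) warning("NaNs produced: log-logistic parameters must be positive",
                   call. = FALSE)
  bad
}

#' @rdname loglogistic
#' @export
dllogis <- function(x, shape, scale) {
  if (bad_llogis_params(shape, scale)) return(rep(NaN, length(x)))
  d <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  if (any(pos)) {
    z <- (x[pos] / scale)^shape
    d[pos] <- (shape / x[pos]) * z / (1 + z)^2
  }
  d[is.na(x)] <- NA_real_
  d
}

#' @rdname loglogistic
#' @export
pllogis <- function(q, shape, scale) {
  if (bad_llogis_params(shape, scale)) return(rep(NaN, length(q)))
  p <- numeric(length(q))
  pos <- is.finite(q) & q > 0
  p[pos] <- 1 / (1 + (q[pos] / scale)^(-shape))
  p[is.infinite(q) & q > 0] <- 1
  p[is.na(q)] <- NA_real_
  p
}

#' @rdname loglogistic
#' @export
qllogis <- function(p, shape, scale) {
  if (bad_llogis_params(shape, scale)) return(rep(NaN, length(p)))
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("'p' must lie strictly within (0, 1)", call. = FALSE)
  scale * (p / (1 - p))^(1 / shape)
}

#' @rdname loglogistic
#' @export
rllogis <- function(n, shape, scale) {
  if (bad_llogis_params(shape, scale)) return(rep(NaN, n))
  qllogis(stats::runif(n), shape = shape, scale = scale)
}
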