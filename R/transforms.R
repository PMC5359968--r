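#' Generalized power transform for predictors
#'
#' Degree-1 fractional-polynomial transform defined for arbitrary real
#' predictors and arbitrary nonzero real powers: \code{x^p} for \code{x > 0},
#' \code{0} at \code{x = 0}, and \code{cos(pi * p) * abs(x)^p} for
#' \code{x < 0}.  The zero power is deliberately rejected: depending on the
#' surrounding model it would act as either a log or a constant transform,
#' and the power searches never propose it.
#'
#' @param x numeric vector.
#' @param p a single nonzero real power.
#' @return numeric vector of transformed values, same length as \code{x}.
#' @examples
#' power_transform(4, 0.5)   # 2
#' power_transform(-2, 2)    # cos(2*pi) * 4 = 4
#' power_transform(c(0, 1, 9), -2)
#' @export
power_transform <- function(x, p) {
  stopifnot(is.numeric(x), length(p) == 1L, is.finite(p))
  if (p == 0)
    stop("power 0 is not a valid predictor transform; use a small nonzero power")
  out <- numeric(length(x))
  pos <- x > 0
  neg <- x < 0
  out[pos] <- x[pos]^p
  out[neg] <- cos(pi * p) * abs(x[neg])^p
  out[is.na(x)] <- NA_real_
  out
}

#' Power transform for positive outcomes
#'
#' Box-Tidwell-type outcome transform: \code{y^p} for \code{p != 0} and
#' \code{log(y)} for \code{p = 0} (the natural-log limit).  Outcomes must be
#' strictly positive; shift non-positive outcomes by a constant before
#' modelling.
#'
#' @param y positive numeric vector.
#' @param p a single real power; \code{0} means natural log.
#' @return numeric vector of transformed values.
#' @examples
#' power_transform_outcome(exp(1), 0)  # 1
#' power_transform_outcome(9, 0.5)     # 3
#' @export
power_transform_outcome <- function(y, p) {
  stopifnot(is.numeric(y), length(p) == 1L, is.finite(p))
  if (any(y <= 0, na.rm = TRUE))
    stop("outcome values must be strictly positive; ",
         "add a constant to shift the variable above zero before transforming")
  if (p == 0) log(y) else y^p
}

#' Power-adjusted normal density for a transformed outcome
#'
#' Density of the untransformed outcome \code{y} when its power transform
#' \code{y^p} (or \code{log y} for \code{p = 0}) is normal with the given
#' mean and variance.  The change of variables contributes the Jacobian
#' factor \code{|p| * y^(p-1)} (\code{1/y} for the log case), which makes
#' likelihoods comparable across different outcome powers.
#'
#' @param y positive numeric vector of outcome values.
#' @param p a single real power (\code{0} = natural log).
#' @param mean,variance mean and (positive) variance of the transformed
#'   outcome; recycled against \code{y}.
#' @param log logical; return the log density (default \code{TRUE}).
#' @return numeric vector of (log) density values.
#' @examples
#' # p = 1 reduces to the ordinary normal density
#' power_density(2.3, 1, mean = 2, variance = 1.5) -
#'   dnorm(2.3, 2, sqrt(1.5), log = TRUE)
#' @export
power_density <- function(y, p, mean, variance, log = TRUE) {
  stopifnot(length(p) == 1L, is.finite(p), all(variance > 0))
  if (any(y <= 0, na.rm = TRUE))
    stop("outcome values must be strictly positive for the power-adjusted density")
  v <- power_transform_outcome(y, p)
  jac <- if (p == 0) -base::log(y) else base::log(abs(p)) + (p - 1) * base::log(y)
  ld <- jac + stats::dnorm(v, mean = mean, sd = sqrt(variance), log = TRUE)
  if (log) ld else exp(ld)
}

# Jacobian term log|d y^p / d y| summed over a vector, used when composing
# power-adjusted likelihoods of the composite model.
log_jacobian <- function(y, p) {
  if (p == 1) return(0)
  if (p == 0) return(-sum(log(y)))
  length(y) * log(abs(p)) + (p - 1) * sum(log(y))
}
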