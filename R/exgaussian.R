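#' Ex-Gaussian parameter set
#'
#' Bundle the three parameters of an ex-Gaussian distribution: the Gaussian
#' mean `mu` and standard deviation `sigma`, and the exponential rate-inverse
#' `tau` that controls the right skew. All three are in milliseconds. The
#' distribution mean is `mu + tau` and its variance `sigma^2 + tau^2`;
#' `tau = 0` degenerates to a plain Gaussian.
#'
#' @param mu Gaussian component mean (ms).
#' @param sigma Gaussian component standard deviation (ms), `>= 0`.
#' @param tau Exponential component mean (ms), `>= 0`.
#' @return An object of class `exgauss_params`.
#' @examples
#' exgauss_params(mu = 500, sigma = 50, tau = 50)
#' @export
exgauss_params <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single finite number >= 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

#' @export
print.exgauss_params <- function(x, ...) {
  cat(sprintf("ex-Gaussian(mu = %g, sigma = %g, tau = %g) ms; mean = %g ms\n",
              x$mu, x$sigma, x$tau, x$mu + x$tau))
  invisible(x)
}

#' Sample from an ex-Gaussian distribution
#'
#' Each draw is a Gaussian(`mu`, `sigma`) deviate plus an independent
#' Exponential(mean `tau`) deviate. With `tau = 0` the exponential component
#' vanishes and the draws are plain Gaussian.
#'
#' @param params An [exgauss_params()] object.
#' @param n Number of draws, `>= 0`.
#' @return Numeric vector of length `n` (milliseconds).
#' @examples
#' set.seed(1)
#' mean(sample_exgaussian(exgauss_params(400, 50, 150), 1e4)) # about 550
#' @export
sample_exgaussian <- function(params, n) {
  if (!inherits(params, "exgauss_params")) params <- do.call(exgauss_params, params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  g <- stats::rnorm(n, mean = params$mu, sd = params$sigma)
  if (params$tau > 0) g <- g + stats::rexp(n, rate = 1 / params$tau)
  g
}

#' Ex-Gaussian density and distribution function
#'
#' Closed-form density and CDF of the ex-Gaussian (Gaussian-exponential
#' convolution), computed on the log scale where possible for numerical
#' stability in the far right tail. Used for model-predicted inhibition
#' functions; the simulator itself only samples.
#'
#' @param x Quantiles (ms).
#' @param params An [exgauss_params()] object.
#' @return Numeric vector of densities (`dexgauss`) or probabilities
#'   (`pexgauss`).
#' @export
dexgauss <- function(x, params) {
  if (!inherits(params, "exgauss_params")) params <- do.call(exgauss_params, params)
  mu <- params$mu; sigma <- params$sigma; tau <- params$tau
  if (tau == 0) return(stats::dnorm(x, mu, sigma))
  if (sigma == 0) return(stats::dexp(x - mu, rate = 1 / tau) * (x >= mu))
  # f(x) = (1/tau) exp((sigma^2/(2 tau^2)) - (x - mu)/tau) *
  #        Phi((x - mu)/sigma - sigma/tau)
  z <- (x - mu) / sigma - sigma / tau
  exp(-log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
        stats::pnorm(z, log.p = TRUE))
}

#' @rdname dexgauss
#' @export
pexgauss <- function(x, params) {
  if (!inherits(params, "exgauss_params")) params <- do.call(exgauss_params, params)
  mu <- params$mu; sigma <- params$sigma; tau <- params$tau
  if (tau == 0) return(stats::pnorm(x, mu, sigma))
  if (sigma == 0) return(stats::pexp(x - mu, rate = 1 / tau))
  u <- (x - mu) / sigma
  z <- u - sigma / tau
  p <- stats::pnorm(u) -
    exp(sigma^2 / (2 * tau^2) - (x - mu) / tau + stats::pnorm(z, log.p = TRUE))
  pmin(pmax(p, 0), 1)
}
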