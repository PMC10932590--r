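#' Exponentially-modified Gaussian (exGaussian) distribution
#'
#' Density, distribution function, and random generation for the exGaussian
#' distribution: the convolution of a Normal(mu, sigma) with an Exponential
#' with mean tau. The exGaussian is the standard heavy-right-tail model for
#' reaction and reading times; `mu` locates the Gaussian component, `sigma`
#' is its dispersion, and `tau` governs rightward skewness. The mean of the
#' distribution is `mu + tau`.
#'
#' The log-density is evaluated in a numerically stable form. Writing
#' `z = (x - mu)/sigma - sigma/tau`, the density is
#' `f(x) = (1/tau) exp((mu - x)/tau + sigma^2/(2 tau^2)) Phi(z)`,
#' and the log is computed with `pnorm(z, log.p = TRUE)`, which remains
#' accurate far into the lower tail (small `tau` relative to `sigma`), where
#' the naive product under- or overflows.
#'
#' @param x numeric vector of quantiles (ms).
#' @param q numeric vector of quantiles (ms).
#' @param n number of draws.
#' @param mu location of the Gaussian component (ms).
#' @param sigma dispersion of the Gaussian component (ms); must be > 0.
#' @param tau mean of the exponential component (ms); must be > 0.
#' @param log,log.p logical; return log density / log probability.
#'
#' @return `dexgauss` the (log-)density, `pexgauss` the (log-)CDF,
#'   `rexgauss` a vector of draws.
#' @examples
#' x <- rexgauss(1000, mu = 300, sigma = 50, tau = 200)
#' mean(x)  # close to 300 + 200
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  stopifnot(all(is.finite(mu)), all(is.finite(sigma)), all(is.finite(tau)))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (any(tau <= 0)) stop("tau must be strictly positive")
  z <- (x - mu) / sigma - sigma / tau
  lf <- -log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm(z, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, log.p = FALSE) {
  if (any(sigma <= 0) || any(tau <= 0)) stop("sigma and tau must be positive")
  u <- (q - mu) / sigma
  # F(q) = Phi(u) - exp(sigma^2/(2 tau^2) - (q - mu)/tau) * Phi(u - sigma/tau)
  lt2 <- sigma^2 / (2 * tau^2) - (q - mu) / tau +
    stats::pnorm(u - sigma / tau, log.p = TRUE)
  p <- stats::pnorm(u) - exp(lt2)
  p <- pmin(pmax(p, 0), 1)
  if (log.p) log(p) else p
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  if (any(sigma <= 0) || any(tau <= 0)) stop("sigma and tau must be positive")
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

# Gradient of the exGaussian log-density with respect to (mu, sigma, tau).
# Uses the inverse Mills ratio r(z) = phi(z)/Phi(z), computed in logs so it is
# stable for z far below zero (where r(z) ~ -z).
exgauss_logpdf_grad <- function(x, mu, sigma, tau) {
  z <- (x - mu) / sigma - sigma / tau
  r <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  dmu <- 1 / tau - r / sigma
  dsigma <- sigma / tau^2 + r * (-(x - mu) / sigma^2 - 1 / tau)
  dtau <- -1 / tau - (mu - x) / tau^2 - sigma^2 / tau^3 + r * sigma / tau^2
  list(mu = dmu, sigma = dsigma, tau = dtau)
}

#' Method-of-moments exGaussian start values
#'
#' Moment-based estimates used to initialize likelihood optimization:
#' `tau = sd * (skew/2)^(1/3)`, `mu = mean - tau`,
#' `sigma^2 = var - tau^2` (clamped away from degeneracy).
#'
#' @param x numeric vector of positive durations (ms).
#' @return named numeric vector `c(mu, sigma, tau)`.
#' @keywords internal
exgauss_moments <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (length(x) < 8L || !is.finite(s) || s == 0) {
    # too few points for stable moments: generic right-skewed start
    return(c(mu = 0.7 * m, sigma = max(0.15 * m, 1), tau = max(0.3 * m, 1)))
  }
  g1 <- mean((x - m)^3) / s^3
  g1 <- max(g1, 0.01)
  tau <- s * (g1 / 2)^(1 / 3)
  tau <- min(tau, 0.95 * s / 0.9)  # keep sigma^2 positive
  sigma2 <- s^2 - tau^2
  sigma <- sqrt(max(sigma2, (0.05 * s)^2))
  c(mu = m - tau, sigma = sigma, tau = max(tau, 0.05 * s))
}

# Stable softplus link and helpers. softplus(x) = log(1 + exp(x)), computed
# without overflow; its inverse and derivative (the logistic sigmoid).
softplus <- function(x) {
  out <- x
  neg <- x <= 30
  out[neg] <- log1p(exp(-abs(x[neg]))) + pmax(x[neg], 0)
  out
}

softplus_inv <- function(y) {
  if (any(y <= 0)) stop("softplus_inv requires positive input")
  out <- y
  small <- y <= 30
  out[small] <- log(expm1(y[small]))
  out
}

softplus_grad <- function(x) stats::plogis(x)
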