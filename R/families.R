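#' Box-Cox transform
#'
#' The one-parameter Box-Cox power transform \eqn{(y^\lambda - 1)/\lambda}
#' (\eqn{\log y} for \eqn{\lambda = 0}), continuous in \eqn{\lambda} at 0.
#'
#' @param y Positive numeric vector.
#' @param lambda Power parameter (scalar or vector recycled against `y`).
#' @return Transformed values.
#' @examples
#' boxcox(4, 0.5)   # (2 - 1)/0.5 = 2
#' boxcox(exp(1), 0)
#' @export
boxcox <- function(y, lambda) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("boxcox() requires strictly positive, finite y")
  n <- max(length(y), length(lambda))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n)
  out <- numeric(n)
  z0 <- lambda == 0
  out[z0] <- log(y[z0])
  out[!z0] <- (y[!z0]^lambda[!z0] - 1) / lambda[!z0]
  out
}

## standardized power-exponential kernel with variance 1; tau = 2 is N(0,1)
.pe_c <- function(tau) sqrt(exp(lgamma(1 / tau) - lgamma(3 / tau)))

.pe_logd <- function(z, tau) {
  cc <- .pe_c(tau)
  log(tau) - log(2 * cc) - lgamma(1 / tau) - (abs(z) / cc)^tau
}

.pe_p <- function(z, tau) {
  cc <- .pe_c(tau)
  0.5 * (1 + sign(z) * stats::pgamma((abs(z) / cc)^tau, shape = 1 / tau))
}

.pe_q <- function(p, tau) {
  cc <- .pe_c(tau)
  sgn <- ifelse(p >= 0.5, 1, -1)
  sgn * cc * stats::qgamma(abs(2 * p - 1), shape = 1 / tau)^(1 / tau)
}

## kernel dispatch: the distribution of the Box-Cox z-score before truncation
.kern_logd <- function(z, tau, family) {
  switch(family,
         BCCG = stats::dnorm(z, log = TRUE),
         BCPE = .pe_logd(z, tau),
         BCT  = stats::dt(z, df = tau, log = TRUE))
}

.kern_p <- function(z, tau, family) {
  switch(family,
         BCCG = stats::pnorm(z),
         BCPE = .pe_p(z, tau),
         BCT  = stats::pt(z, df = tau))
}

.kern_q <- function(p, tau, family) {
  switch(family,
         BCCG = stats::qnorm(p),
         BCPE = .pe_q(p, tau),
         BCT  = stats::qt(p, df = tau))
}

.bc_z <- function(y, mu, sigma, lambda) {
  z <- numeric(length(y))
  z0 <- lambda == 0
  z[z0] <- log(y[z0] / mu[z0]) / sigma[z0]
  z[!z0] <- ((y[!z0] / mu[!z0])^lambda[!z0] - 1) / (lambda[!z0] * sigma[!z0])
  z
}

.recycle <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 1L))
  lapply(args, rep_len, n)
}

## positive-support normalization constant C = F_z(1/(sigma*|lambda|))
.bc_C <- function(sigma, lambda, tau, family) {
  C <- rep(1, length(sigma))
  nz <- lambda != 0
  if (any(nz))
    C[nz] <- .kern_p(1 / (sigma[nz] * abs(lambda[nz])), tau[nz], family)
  C
}

.fam_check <- function(y, mu, sigma, tau, family) {
  if (!family %in% c("BCCG", "BCPE", "BCT"))
    stop("unknown family: ", family)
  if (any(y <= 0) || any(!is.finite(y))) stop("y must be positive and finite")
  if (any(mu <= 0) || any(sigma <= 0)) stop("mu and sigma must be positive")
  if (family != "BCCG" && any(tau <= 0)) stop("tau must be positive")
}

#' Log-density of the Box-Cox distribution families
#'
#' Density of the BCCG (Box-Cox Cole-Green, the LMS model), BCPE (Box-Cox
#' power exponential) and BCT (Box-Cox t) distributions on \eqn{(0,\infty)}.
#' The Box-Cox z-score \eqn{z = ((y/\mu)^\lambda - 1)/(\lambda\sigma)}
#' follows a standard normal (BCCG), unit-variance power exponential with
#' kurtosis parameter \eqn{\tau} (BCPE; \eqn{\tau = 2} recovers BCCG), or a
#' Student-t with \eqn{\tau} degrees of freedom (BCT), truncated to the
#' region compatible with \eqn{y > 0}.
#'
#' @param family One of `"BCCG"`, `"BCPE"`, `"BCT"`.
#' @param y Positive values (analyte units).
#' @param mu Location (> 0): the (approximate) median.
#' @param sigma Scale (> 0): approximate coefficient of variation.
#' @param lambda Skewness: the Box-Cox power.
#' @param tau Kurtosis parameter (> 0); ignored for BCCG.
#' @return Log-density values.
#' @export
family_log_density <- function(family, y, mu, sigma, lambda, tau = 2) {
  a <- .recycle(y, mu, sigma, lambda, tau)
  y <- a[[1]]; mu <- a[[2]]; sigma <- a[[3]]; lambda <- a[[4]]; tau <- a[[5]]
  .fam_check(y, mu, sigma, tau, family)
  z <- .bc_z(y, mu, sigma, lambda)
  C <- .bc_C(sigma, lambda, tau, family)
  (lambda - 1) * log(y) - lambda * log(mu) - log(sigma) +
    .kern_logd(z, tau, family) - log(C)
}

#' Cumulative distribution function of the Box-Cox families
#'
#' @inheritParams family_log_density
#' @return Probabilities in \[0, 1\].
#' @export
family_cdf <- function(family, y, mu, sigma, lambda, tau = 2) {
  a <- .recycle(y, mu, sigma, lambda, tau)
  y <- a[[1]]; mu <- a[[2]]; sigma <- a[[3]]; lambda <- a[[4]]; tau <- a[[5]]
  .fam_check(y, mu, sigma, tau, family)
  z <- .bc_z(y, mu, sigma, lambda)
  Fz <- .kern_p(z, tau, family)
  C <- .bc_C(sigma, lambda, tau, family)
  p <- Fz                                  # lambda == 0
  pos <- lambda > 0
  neg <- lambda < 0
  p[pos] <- (Fz[pos] - (1 - C[pos])) / C[pos]
  p[neg] <- Fz[neg] / C[neg]
  pmin(1, pmax(0, p))
}

#' Quantile function of the Box-Cox families
#'
#' Strictly increasing in `p`; inverse of [family_cdf()] to numerical
#' round-off.
#'
#' @inheritParams family_log_density
#' @param p Probabilities in (0, 1).
#' @return Quantiles (positive values).
#' @export
family_quantile <- function(family, p, mu, sigma, lambda, tau = 2) {
  a <- .recycle(p, mu, sigma, lambda, tau)
  p <- a[[1]]; mu <- a[[2]]; sigma <- a[[3]]; lambda <- a[[4]]; tau <- a[[5]]
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly in (0, 1)")
  .fam_check(1, mu, sigma, tau, family)
  C <- .bc_C(sigma, lambda, tau, family)
  ## map p to the kernel scale, undoing the truncation
  pk <- p
  pos <- lambda > 0
  neg <- lambda < 0
  pk[pos] <- 1 - C[pos] * (1 - p[pos])
  pk[neg] <- p[neg] * C[neg]
  z <- .kern_q(pk, tau, family)
  y <- numeric(length(p))
  z0 <- lambda == 0
  y[z0] <- mu[z0] * exp(sigma[z0] * z[z0])
  base <- 1 + lambda[!z0] * sigma[!z0] * z[!z0]
  if (any(base <= 0))
    stop("quantile undefined: Box-Cox domain edge reached")
  y[!z0] <- mu[!z0] * base^(1 / lambda[!z0])
  y
}

#' @rdname family_log_density
#' @export
dbccg <- function(y, mu, sigma, lambda, log = FALSE) {
  ld <- family_log_density("BCCG", y, mu, sigma, lambda)
  if (log) ld else exp(ld)
}

#' @rdname family_cdf
#' @export
pbccg <- function(y, mu, sigma, lambda)
  family_cdf("BCCG", y, mu, sigma, lambda)

#' @rdname family_quantile
#' @export
qbccg <- function(p, mu, sigma, lambda)
  family_quantile("BCCG", p, mu, sigma, lambda)

#' @rdname family_log_density
#' @export
dbcpe <- function(y, mu, sigma, lambda, tau, log = FALSE) {
  ld <- family_log_density("BCPE", y, mu, sigma, lambda, tau)
  if (log) ld else exp(ld)
}

#' @rdname family_cdf
#' @export
pbcpe <- function(y, mu, sigma, lambda, tau)
  family_cdf("BCPE", y, mu, sigma, lambda, tau)

#' @rdname family_quantile
#' @export
qbcpe <- function(p, mu, sigma, lambda, tau)
  family_quantile("BCPE", p, mu, sigma, lambda, tau)

#' @rdname family_log_density
#' @export
dbct <- function(y, mu, sigma, lambda, tau, log = FALSE) {
  ld <- family_log_density("BCT", y, mu, sigma, lambda, tau)
  if (log) ld else exp(ld)
}

#' @rdname family_cdf
#' @export
pbct <- function(y, mu, sigma, lambda, tau)
  family_cdf("BCT", y, mu, sigma, lambda, tau)

#' @rdname family_quantile
#' @export
qbct <- function(p, mu, sigma, lambda, tau)
  family_quantile("BCT", p, mu, sigma, lambda, tau)
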