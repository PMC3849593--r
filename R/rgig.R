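#' Generalized inverse Gaussian random variates
#'
#' Draws from the generalized inverse Gaussian (GIG) distribution with density
#' \deqn{f(x) \propto x^{\lambda-1} \exp\{-(\chi/x + \psi x)/2\}, \quad x > 0.}
#' This is the full conditional of each per-coefficient prior variance in the
#' Normal-Gamma hierarchy (with \eqn{\lambda = \lambda_j - 1/2},
#' \eqn{\chi = \beta_{j,i}^2}, \eqn{\psi = \gamma_j^{-2}}) and of the
#' Bayesian-lasso variance (with \eqn{\lambda = 1/2}).
#'
#' Sampling uses a rejection algorithm on the log scale (Devroye-family): the
#' log density of \eqn{\log(X/m)}, \eqn{m} the mode, is concave and is
#' dominated by a flat centre piece with two exponential tails. Negative
#' \eqn{\lambda} is handled by the inversion identity
#' \eqn{1/X \sim GIG(-\lambda, \psi, \chi)}; \eqn{\chi = 0} with
#' \eqn{\lambda > 0} reduces to a Gamma(\eqn{\lambda}, rate \eqn{\psi/2}) draw.
#'
#' @param n number of draws.
#' @param lambda shape exponent (any real).
#' @param chi non-negative; weight of the \eqn{1/x} term.
#' @param psi non-negative; weight of the \eqn{x} term.
#'
#' @return Numeric vector of `n` positive draws. Parameters are recycled.
#' @examples
#' set.seed(1)
#' x <- rgig(1000, lambda = 0.5, chi = 1, psi = 1)
#' mean(x)
#' @export
rgig <- function(n, lambda, chi, psi) {
  stopifnot(n >= 0, length(lambda) >= 1, length(chi) >= 1, length(psi) >= 1)
  if (any(!is.finite(lambda)) || any(!is.finite(chi)) || any(!is.finite(psi)))
    stop("rgig: parameters must be finite")
  .rgig_cpp(as.integer(n), as.numeric(lambda), as.numeric(chi), as.numeric(psi))
}

#' Generalized inverse Gaussian density
#'
#' Normalized density of the GIG distribution in the same parameterization as
#' [rgig()]. The normalizing constant uses the modified Bessel function of the
#' second kind, \eqn{(\psi/\chi)^{\lambda/2} / \{2 K_\lambda(\sqrt{\chi\psi})\}}.
#'
#' @inheritParams rgig
#' @param x vector of positive evaluation points.
#' @param log if `TRUE`, return the log density.
#' @return Numeric vector of densities.
#' @export
dgig <- function(x, lambda, chi, psi, log = FALSE) {
  stopifnot(chi > 0, psi > 0)
  omega <- sqrt(chi * psi)
  lc <- (lambda / 2) * log(psi / chi) - log(2) -
    log(besselK(omega, lambda, expon.scaled = TRUE)) + omega
  ld <- lc + (lambda - 1) * log(x) - (chi / x + psi * x) / 2
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}
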