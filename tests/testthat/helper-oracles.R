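# Independent oracles shared across tests. Everything here is computed from
# first principles (quadrature, Bessel identities, normal equations), never
# through the package's own sampling code paths.

# k-th raw moment of GIG(lambda, chi, psi) via the Bessel-function identity
# E[X^k] = (chi/psi)^{k/2} K_{lambda+k}(omega) / K_lambda(omega)
gig_moment <- function(k, lambda, chi, psi) {
  omega <- sqrt(chi * psi)
  (chi / psi)^(k / 2) *
    besselK(omega, lambda + k, expon.scaled = TRUE) /
    besselK(omega, lambda, expon.scaled = TRUE)
}

# unnormalized GIG density
gig_kernel <- function(x, lambda, chi, psi) {
  x^(lambda - 1) * exp(-(chi / x + psi * x) / 2)
}

# normalizing constant by quadrature
gig_norm_const <- function(lambda, chi, psi) {
  integrate(gig_kernel, 0, Inf, lambda = lambda, chi = chi, psi = psi,
            rel.tol = 1e-10)$value
}

# quadrature CDF of the GIG, vectorized over q
gig_cdf_quad <- function(q, lambda, chi, psi) {
  z <- gig_norm_const(lambda, chi, psi)
  vapply(q, function(qi) {
    if (qi <= 0) return(0)
    integrate(gig_kernel, 0, qi, lambda = lambda, chi = chi, psi = psi,
              rel.tol = 1e-9)$value / z
  }, numeric(1))
}

# raw moment of the GIG by quadrature (independent of the Bessel identity)
gig_moment_quad <- function(k, lambda, chi, psi) {
  z <- gig_norm_const(lambda, chi, psi)
  integrate(function(x) x^k * gig_kernel(x, lambda, chi, psi), 0, Inf,
            rel.tol = 1e-9)$value / z
}

# normal-equations least squares (oracle for coefficient fits)
normal_eq_coef <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# build a minimal ng_chain object around a draw matrix (for selection tests)
fake_chain <- function(beta_draws, annotation = NULL) {
  structure(list(beta = beta_draws, sigma2 = rep(1, nrow(beta_draws)),
                 n_iter = nrow(beta_draws), burn_in = 0, y_center = 0,
                 method = "normal-gamma", annotation = annotation),
            class = "ng_chain")
}

# data matrix whose sample covariance has exactly the requested eigenvalues
matrix_with_spectrum <- function(n, eigenvalues, seed = 1) {
  set.seed(seed)
  p <- length(eigenvalues)
  X <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  sv <- svd(X)
  sv$u %*% diag(sqrt(eigenvalues * (n - 1))) %*% t(sv$v)
}

# small aligned multi-platform toy dataset built in code
toy_dataset <- function(n = 12, seed = 99) {
  set.seed(seed)
  samples <- sprintf("P%02d", seq_len(n))
  mrna <- matrix(rnorm(n * 2), n, 2,
                 dimnames = list(samples, c("GENE1", "GENE2")))
  meth <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(samples, c("m1", "m2", "m3")))
  cn <- matrix(rnorm(n * 2), n, 2, dimnames = list(samples, c("c1", "c2")))
  list(
    mrna = mrna, meth = meth, cn = cn,
    meth_map = marker_map(c("m1", "m2", "m3"),
                          c("GENE1", "GENE1", "GENE2")),
    cn_map = marker_map(c("c1", "c2"), c("GENE1", "GENE2")),
    survival = stats::setNames(exp(rnorm(n, log(365), 0.5)), samples)
  )
}
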