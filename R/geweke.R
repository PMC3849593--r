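# batch-means standard error for a (possibly autocorrelated) chain
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  sd(means) / sqrt(n_batch)
}

# one forward draw of all model parameters from the prior hierarchy
ng_prior_draw <- function(p, hyper) {
  lambda <- rexp(1, rate = hyper$c)
  gamma_inv2 <- rgamma(1, shape = hyper$a_tilde,
                       rate = hyper$b_tilde / (2 * lambda))
  psi <- rgamma(p, shape = lambda, rate = gamma_inv2 / 2)
  psi <- pmax(psi, 1e-300)
  beta <- rnorm(p, 0, sqrt(psi))
  sigma2 <- 1 / rgamma(1, shape = hyper$a, rate = hyper$b)
  list(beta = beta, sigma2 = sigma2, psi = psi, lambda = lambda,
       gamma_inv2 = gamma_inv2)
}

#' Joint-distribution validation of the Normal-Gamma sampler
#'
#' Getting-it-right style check on a tiny instance: the first and second
#' moments of \eqn{\beta_1}, \eqn{\sigma^2} and \eqn{\lambda_1} are estimated
#' two ways — (i) marginal-conditional: iid draws of the parameters from the
#' prior hierarchy; (ii) successive-conditional: a chain that alternates one
#' full Gibbs scan (all complete conditionals plus the fixed-scale MH step
#' for \eqn{\lambda}) with a fresh draw of the data given the parameters. If
#' every update targets its stated conditional, both routes sample the same
#' joint law and all moments agree up to Monte Carlo error.
#'
#' Proper hyperparameters with finite fourth moments are required for a
#' moment test, so the defaults here are informative (`a = 6, b = 5,
#' a_tilde = 3, b_tilde = 1`) rather than the analysis defaults; the update
#' code paths are identical.
#'
#' @param n,p data size of the tiny instance.
#' @param n_draws draws per route (after discarding a tenth of the chain).
#' @param hyper list with entries `a`, `b`, `c`, `a_tilde`, `b_tilde` (all
#'   fixed constants here).
#' @param tuning fixed MH scale (no adaptation, so the chain is homogeneous).
#' @param seed integer seed.
#' @return Tibble with one row per checked moment: the two estimates, their
#'   standard errors (batch means for the chain) and the combined z score.
#' @export
geweke_check <- function(n = 10, p = 3, n_draws = 20000,
                         hyper = list(a = 6, b = 5, c = 1, a_tilde = 3,
                                      b_tilde = 1),
                         tuning = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  XtX <- crossprod(X)
  groups <- rep(1L, p)

  # route 1: iid prior draws
  fwd <- matrix(NA_real_, n_draws, 3)
  for (s in seq_len(n_draws)) {
    th <- ng_prior_draw(p, hyper)
    fwd[s, ] <- c(th$beta[1], th$sigma2, th$lambda)
  }

  # route 2: successive-conditional chain
  burn <- ceiling(n_draws / 10)
  total <- n_draws + burn
  chain <- matrix(NA_real_, n_draws, 3)
  th <- ng_prior_draw(p, hyper)
  for (s in seq_len(total)) {
    y <- drop(X %*% th$beta) + rnorm(n, sd = sqrt(th$sigma2))
    Xty <- drop(crossprod(X, y))
    th$beta <- update_beta(XtX, Xty, th$sigma2, th$psi)
    th$sigma2 <- update_sigma2(y - drop(X %*% th$beta), hyper$a, hyper$b)
    th$psi <- update_psi(th$beta, th$lambda, th$gamma_inv2, groups)
    th$gamma_inv2 <- update_gamma_inv2(th$psi, th$lambda, groups,
                                       hyper$a_tilde, hyper$b_tilde)
    up <- update_lambda(th$lambda, th$psi, th$gamma_inv2, tuning,
                        hyper$a_tilde, hyper$b_tilde, hyper$c)
    th$lambda <- up$lambda
    if (s > burn) chain[s - burn, ] <- c(th$beta[1], th$sigma2, th$lambda)
  }

  quantities <- c("beta1", "beta1^2", "sigma2", "sigma2^2", "lambda1",
                  "lambda1^2")
  fun <- list(function(m) m[, 1], function(m) m[, 1]^2,
              function(m) m[, 2], function(m) m[, 2]^2,
              function(m) m[, 3], function(m) m[, 3]^2)
  purrr::map_dfr(seq_along(quantities), function(i) {
    a <- fun[[i]](fwd); b <- fun[[i]](chain)
    se_a <- sd(a) / sqrt(length(a))
    se_b <- batch_se(b)
    tibble::tibble(
      quantity = quantities[i],
      forward_mean = mean(a), forward_se = se_a,
      chain_mean = mean(b), chain_se = se_b,
      z = (mean(a) - mean(b)) / sqrt(se_a^2 + se_b^2)
    )
  })
}
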