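test_that("beta conditional matches the scalar closed form", {
  # p = 1, X = (1,1)', Y = (2,4)', sigma2 = 1, psi = 1:
  # mean = X'Y/(X'X + 1) = 2, var = 1/3
  XtX <- matrix(2, 1, 1)
  Xty <- 6
  set.seed(41)
  draws <- replicate(20000, update_beta(XtX, Xty, sigma2 = 1, psi = 1))
  expect_lt(abs(mean(draws) - 2), 4 * sqrt(1 / 3 / 20000))
  expect_lt(abs(var(draws) - 1 / 3), 4 * sqrt(2 / 3^2 / 20000))

  # psi -> Inf recovers the least-squares mean (here the sample mean of Y)
  set.seed(42)
  d2 <- replicate(5000, update_beta(XtX, Xty, sigma2 = 1, psi = 1e12))
  expect_lt(abs(mean(d2) - 3), 4 * sqrt(0.5 / 5000))
})

test_that("sigma2 conditional has the stated inverse-gamma law", {
  # a' = a + n/2 = 5, scale = b + rss/2 = 4 -> mean 1, var 1/3
  resid <- c(2, 2, 0, 0)            # rss = 8
  set.seed(43)
  draws <- replicate(20000, update_sigma2(resid, a = 3, b = 0))
  expect_lt(abs(mean(draws) - 1), 4 * sqrt(1 / 3 / 20000))

  # zero residuals with the uninformative prior: Inv.Gamma(a + n/2, b)
  set.seed(44)
  d0 <- replicate(20000, update_sigma2(rep(0, 4), a = 0.001, b = 0.001))
  expect_lt(abs(mean(d0) - 0.001 / 1.001), 4 * 1e-3 / sqrt(20000))

  set.seed(45); s1 <- update_sigma2(resid)
  set.seed(45); s2 <- update_sigma2(resid)
  expect_identical(s1, s2)
})

test_that("psi conditional reduces to a gamma when beta is zero", {
  # beta = 0 (floored chi), lambda_j = 2 -> shape p = 1.5, rate a/2 = 0.5
  set.seed(46)
  draws <- update_psi(rep(0, 50000), lambda = 2, gamma_inv2 = 1,
                      groups = rep(1L, 50000))
  expect_lt(abs(mean(draws) - 3), 4 * sqrt(6 / 50000))
  expect_true(all(draws > 0))
})

test_that("gamma_inv2 conditional is the conjugate gamma", {
  # shape = p_j lambda + a_tilde = 3, rate = (b_tilde/lambda + sum psi)/2 = 2
  set.seed(47)
  draws <- replicate(20000, update_gamma_inv2(psi = 2, lambda = 1,
                                              groups = 1L, a_tilde = 2,
                                              b_tilde = 2))
  expect_lt(abs(mean(draws) - 1.5), 4 * sqrt(3 / 4 / 20000))

  # conjugacy on a grid: prior x likelihood renormalized matches the stated law
  lambda <- 1.3; b_tilde <- 0.7; a_tilde <- 2; psi <- c(0.5, 2.2, 1.1)
  g <- seq(0.001, 30, length.out = 20000)
  unnorm <- stats::dgamma(g, a_tilde, rate = b_tilde / (2 * lambda)) *
    vapply(g, function(gi) {
      prod(stats::dgamma(psi, shape = lambda, rate = gi / 2))
    }, numeric(1))
  dens <- unnorm / sum(unnorm * diff(g)[1])
  stated <- stats::dgamma(g, shape = 3 * lambda + a_tilde,
                          rate = (b_tilde / lambda + sum(psi)) / 2)
  expect_lt(max(abs(dens - stated)), 1e-3)
})

test_that("lambda MH acceptance ratio is exact in log space", {
  psi_j <- c(0.4, 1.7, 0.9)
  gamma_inv2 <- 1.4; a_tilde <- 2; b_tilde <- 0.8; cc <- 1
  lam <- 0.9; lam_star <- 1.7
  # direct (non-log) evaluation of the printed ratio
  pi_fn <- function(l) (1 / l)^a_tilde * exp(-b_tilde * gamma_inv2 / (2 * l) - cc * l)
  direct <- pi_fn(lam_star) / pi_fn(lam) *
    (gamma(lam) / gamma(lam_star))^3 *
    (2 / gamma_inv2)^(-3 * (lam_star - lam)) *
    prod(psi_j)^(lam_star - lam) *
    lam_star / lam
  la <- lambda_log_acceptance(lam_star, lam, 3, sum(log(psi_j)), gamma_inv2,
                              a_tilde, b_tilde, cc)
  expect_lt(abs(la - log(direct)), 1e-10)

  # identical proposal accepted with probability one
  expect_equal(lambda_log_acceptance(lam, lam, 3, sum(log(psi_j)),
                                     gamma_inv2, a_tilde, b_tilde, cc), 0)
})

test_that("MH tuning moves toward the target band and stays put inside it", {
  expect_identical(tune_mh(0.5, 0.25), 0.5)
  expect_gt(tune_mh(0.5, 0.50), 0.5)
  expect_lt(tune_mh(0.5, 0.05), 0.5)
})

test_that("initialization follows the stated recipe", {
  set.seed(48)
  n <- 60; p <- 5
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))  # orthonormal columns
  beta_true <- c(2, 0, -1, 0, 0)
  y <- drop(X %*% beta_true) + rnorm(n, sd = 0.3)
  st <- initialize_state(X, y, rep(1L, p))
  expect_identical(st$psi, rep(1, p))
  expect_identical(st$lambda, 1)
  expect_identical(st$gamma_inv2, 1)
  # b_tilde = mean of squared OLS coefficients (normal-equations oracle)
  expect_equal(st$b_tilde, mean(normal_eq_coef(X, y)^2), tolerance = 1e-8)
  expect_equal(st$sigma2, mean((y - drop(X %*% st$beta))^2), tolerance = 1e-10)

  # pure noise: the lasso start is (near) empty
  set.seed(49)
  Xn <- matrix(rnorm(100 * 20), 100, 20)
  yn <- rnorm(100)
  st0 <- initialize_state(Xn, yn, rep(1L, 20))
  expect_lt(mean(abs(st0$beta)), 0.2)
})

test_that("chains are bitwise reproducible under a fixed seed", {
  set.seed(50)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  g <- rep(1:2, each = 3)
  c1 <- ng_regress(X, y, g, n_iter = 150, burn_in = 50, seed = 7)
  c2 <- ng_regress(X, y, g, n_iter = 150, burn_in = 50, seed = 7)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$sigma2, c2$sigma2)
  b1 <- blasso_regress(X, y, g, n_iter = 150, burn_in = 50, seed = 7)
  b2 <- blasso_regress(X, y, g, n_iter = 150, burn_in = 50, seed = 7)
  expect_identical(b1$beta, b2$beta)
})

test_that("scale parameters stay positive across the whole chain", {
  set.seed(51)
  X <- matrix(rnorm(50 * 9), 50, 9)
  y <- drop(X[, 1] * 1.5) + rnorm(50)
  ch <- ng_regress(X, y, rep(1:3, each = 3), n_iter = 400, burn_in = 100,
                   seed = 3)
  expect_true(all(ch$sigma2 > 0))
  expect_true(all(ch$lambda > 0))
  expect_true(all(ch$gamma_inv2 > 0))
  expect_true(all(is.finite(ch$beta)))
})

test_that("the sampler recovers parameters of a well-posed model", {
  set.seed(52)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  beta_true <- c(2, 0, -2)
  y <- drop(X %*% beta_true) + rnorm(n)
  ch <- ng_regress(X, y, rep(1L, 3), n_iter = 3000, burn_in = 500, seed = 9)
  pm <- colMeans(ch$beta)
  psd <- apply(ch$beta, 2, sd)
  expect_true(all(abs(pm - beta_true) < 3 * psd + 1e-8))
  expect_lt(abs(mean(ch$sigma2) - 1), 0.3)
})

test_that("the Bayesian-lasso psi conditional matches its GIG form on a grid", {
  # density prop to psi^{-1/2} exp(-beta^2/(2 psi) - lambda psi):
  # GIG(lambda = 1/2, chi = beta^2, psi = 2 lambda_rate)
  beta <- 0.8; lam <- 1.6
  g <- seq(1e-4, 25, length.out = 20000)
  unnorm <- g^(-0.5) * exp(-beta^2 / (2 * g) - lam * g)
  dens <- unnorm / (sum(unnorm) * diff(g)[1])
  stated <- dgig(g, lambda = 0.5, chi = beta^2, psi = 2 * lam)
  expect_lt(max(abs(dens - stated)), 1e-3)
})

test_that("chain summaries match sort-based percentile oracles", {
  set.seed(53)
  draws <- matrix(rnorm(4000), 2000, 2)
  draws[, 2] <- draws[, 2] * 3 + 1
  ch <- fake_chain(draws)
  s <- summarize_chain(ch, levels = 0.95)
  srt <- sort(draws[, 2])
  expect_equal(s$conf.low.95[2],
               unname(quantile(srt, 0.025)), tolerance = 1e-12)
  expect_equal(s$conf.high.95[2],
               unname(quantile(srt, 0.975)), tolerance = 1e-12)
  expect_equal(s$estimate, colMeans(draws), ignore_attr = TRUE)

  # constant draws collapse the interval to a point
  cc <- fake_chain(matrix(2, 100, 1))
  sc <- summarize_chain(cc, levels = 0.9)
  expect_identical(sc$conf.low.9, sc$conf.high.9)

  g <- glance(ch)
  expect_identical(g$n_draws, 2000L)
})

test_that("truly zero coefficients are shrunk harder than least squares", {
  dat <- generate_table1_data(seed = 54)
  ch <- ng_regress(dat$train$X, dat$train$y, dat$groups, n_iter = 2000,
                   burn_in = 500, seed = 55)
  ols <- fit_least_squares(dat$train$X, dat$train$y)
  zero <- dat$zero_idx
  expect_lt(mean(abs(colMeans(ch$beta)[zero])), mean(abs(ols$beta[zero])))
})
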