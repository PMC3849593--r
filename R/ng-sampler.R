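#' Hyperparameters of the Normal-Gamma clinical model
#'
#' The hierarchy is \deqn{Y \sim N(X\beta, \sigma^2 I), \quad
#' \beta_{j,i} \sim N(0, \psi_{j,i}), \quad
#' \psi_{j,i} \sim Gamma(\lambda_j, rate = 1/(2\gamma_j^2)),}
#' \deqn{\sigma^2 \sim InvGamma(a, b), \quad \lambda_j \sim Exp(c), \quad
#' \gamma_j^{-2} \sim Gamma(\tilde a, rate = \tilde b/(2\lambda_j)).}
#'
#' Defaults: `a = b = 0.001` (uninformative error variance), `c = 1`,
#' `a_tilde = 2`; `b_tilde = NULL` means data-driven — the mean of the squared
#' (ridge-stabilized) least-squares coefficients, computed at initialization.
#'
#' @param a,b inverse-gamma shape/scale for the error variance.
#' @param c exponential rate for each platform shape \eqn{\lambda_j}.
#' @param a_tilde gamma shape for \eqn{\gamma_j^{-2}}.
#' @param b_tilde scale constant of the \eqn{\gamma_j^{-2}} prior rate;
#'   `NULL` = set from the data at initialization.
#' @return List of class `ng_hyperparams`.
#' @export
ng_hyperparams <- function(a = 0.001, b = 0.001, c = 1, a_tilde = 2,
                           b_tilde = NULL) {
  stopifnot(a > 0, b > 0, c > 0, a_tilde > 0,
            is.null(b_tilde) || b_tilde > 0)
  structure(list(a = a, b = b, c = c, a_tilde = a_tilde, b_tilde = b_tilde),
            class = "ng_hyperparams")
}

# Cholesky with escalating jitter; A must be symmetric
chol_jitter <- function(A, max_tries = 5) {
  jit <- 0
  for (i in seq_len(max_tries)) {
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (!is.null(U)) return(U)
    jit <- if (jit == 0) 1e-8 * mean(diag(A)) else jit * 10
    warning("Cholesky failed; retrying with jitter ", signif(jit, 3),
            call. = FALSE)
    diag(A) <- diag(A) + jit
  }
  stop("Cholesky factorization failed after jitter retries")
}

#' Draw the regression coefficients from their full conditional
#'
#' Exact multivariate-normal draw with mean
#' \eqn{(X'X + \sigma^2 D_\psi^{-1})^{-1} X'Y} and covariance
#' \eqn{\sigma^2 (X'X + \sigma^2 D_\psi^{-1})^{-1}}, computed through a
#' Cholesky factorization of the precision-like matrix (jitter retry on
#' failure). `XtX` and `Xty` are passed precomputed since they are constant
#' across iterations.
#'
#' @param XtX cross-product matrix \eqn{X'X} (p x p).
#' @param Xty vector \eqn{X'Y} (length p).
#' @param sigma2 current error variance.
#' @param psi current vector of prior variances (length p, positive).
#' @return Vector of length p.
#' @export
update_beta <- function(XtX, Xty, sigma2, psi) {
  p <- length(Xty)
  A <- XtX
  diag(A) <- diag(XtX) + sigma2 / psi
  U <- chol_jitter(A)
  m <- backsolve(U, backsolve(U, Xty, transpose = TRUE))
  drop(m + sqrt(sigma2) * backsolve(U, rnorm(p)))
}

#' Draw the error variance from its full conditional
#'
#' Inverse-gamma with shape \eqn{a + n/2} and scale
#' \eqn{b + (Y - X\beta)'(Y - X\beta)/2}.
#'
#' @param resid residual vector \eqn{Y - X\beta}.
#' @param a,b prior shape and scale.
#' @return Positive scalar.
#' @export
update_sigma2 <- function(resid, a = 0.001, b = 0.001) {
  1 / rgamma(1, shape = a + length(resid) / 2,
             rate = b + sum(resid^2) / 2)
}

#' Draw the per-coefficient prior variances from their GIG conditionals
#'
#' Each \eqn{\psi_{j,i}} follows a generalized inverse Gaussian with
#' \eqn{\chi = \beta_{j,i}^2}, \eqn{\psi = \gamma_j^{-2}} and shape exponent
#' \eqn{\lambda_j - 1/2}. A numerically zero \eqn{\beta_{j,i}^2} is floored at
#' `1e-12` to keep the distribution proper when the shape exponent is
#' non-positive.
#'
#' @param beta current coefficient vector.
#' @param lambda per-platform shape vector (length J).
#' @param gamma_inv2 per-platform \eqn{\gamma_j^{-2}} vector (length J).
#' @param groups integer vector mapping each coefficient to its platform.
#' @return Vector of positive variances, same length as `beta`.
#' @export
update_psi <- function(beta, lambda, gamma_inv2, groups) {
  rgig(length(beta),
       lambda = lambda[groups] - 0.5,
       chi = pmax(beta^2, 1e-12),
       psi = gamma_inv2[groups])
}

#' Draw the platform scale parameters from their gamma conditionals
#'
#' \eqn{\gamma_j^{-2}} is gamma with shape \eqn{p_j \lambda_j + \tilde a} and
#' rate \eqn{(\tilde b/\lambda_j + \sum_i \psi_{j,i})/2}.
#'
#' @param psi current prior-variance vector.
#' @param lambda per-platform shape vector.
#' @param groups platform index per coefficient.
#' @param a_tilde,b_tilde hyperparameters of the \eqn{\gamma_j^{-2}} prior.
#' @return Vector of length J (number of platforms).
#' @export
update_gamma_inv2 <- function(psi, lambda, groups, a_tilde = 2, b_tilde = 1) {
  J <- length(lambda)
  p_j <- tabulate(groups, nbins = J)
  sum_psi <- vapply(seq_len(J), function(j) sum(psi[groups == j]), numeric(1))
  rgamma(J, shape = p_j * lambda + a_tilde,
         rate = (b_tilde / lambda + sum_psi) / 2)
}

#' Log acceptance ratio of the Metropolis-Hastings step for lambda_j
#'
#' The platform shape \eqn{\lambda_j} has no closed-form conditional; a
#' multiplicative log-normal random walk is used. The log acceptance ratio is
#' \deqn{\log\pi(\lambda^*) - \log\pi(\lambda) +
#'   p_j\{\log\Gamma(\lambda) - \log\Gamma(\lambda^*)\}
#'   - p_j(\lambda^*-\lambda)\log(2\gamma_j^2)
#'   + (\lambda^*-\lambda)\sum_i \log\psi_{j,i} + \log(\lambda^*/\lambda),}
#' with prior \eqn{\pi(\lambda) = \lambda^{-\tilde a}
#' \exp\{-\tilde b\gamma_j^{-2}/(2\lambda) - c\lambda\}}; the last term is the
#' proposal Jacobian.
#'
#' @param lambda_star proposed value.
#' @param lambda current value.
#' @param p_j number of coefficients in the platform.
#' @param sum_log_psi sum of log prior variances in the platform.
#' @param gamma_inv2 current \eqn{\gamma_j^{-2}} for the platform.
#' @param a_tilde,b_tilde,c hyperparameters.
#' @return Scalar log acceptance ratio.
#' @export
lambda_log_acceptance <- function(lambda_star, lambda, p_j, sum_log_psi,
                                  gamma_inv2, a_tilde = 2, b_tilde = 1,
                                  c = 1) {
  log_prior <- function(l) -a_tilde * log(l) - b_tilde * gamma_inv2 / (2 * l) - c * l
  log_prior(lambda_star) - log_prior(lambda) +
    p_j * (lgamma(lambda) - lgamma(lambda_star)) -
    p_j * (lambda_star - lambda) * (log(2) - log(gamma_inv2)) +
    (lambda_star - lambda) * sum_log_psi +
    log(lambda_star) - log(lambda)
}

#' Metropolis-Hastings update of one platform's lambda_j
#'
#' Proposes \eqn{\lambda_j^* = \exp(\sigma_\lambda z)\lambda_j},
#' \eqn{z \sim N(0,1)}, and accepts with the ratio of
#' [lambda_log_acceptance()], evaluated in log space. Proposals escaping the
#' support guard `[1e-6, 1e6]` are rejected (they would overflow the gamma
#' function).
#'
#' @param lambda current value.
#' @param psi_j prior variances of this platform's coefficients.
#' @param gamma_inv2 current \eqn{\gamma_j^{-2}} for the platform.
#' @param tuning_sigma random-walk scale (> 0).
#' @param a_tilde,b_tilde,c hyperparameters.
#' @return List with `lambda` (new value) and `accepted` (logical).
#' @export
update_lambda <- function(lambda, psi_j, gamma_inv2, tuning_sigma,
                          a_tilde = 2, b_tilde = 1, c = 1) {
  stopifnot(tuning_sigma > 0)
  lambda_star <- exp(tuning_sigma * rnorm(1)) * lambda
  if (lambda_star < 1e-6 || lambda_star > 1e6) {
    return(list(lambda = lambda, accepted = FALSE))
  }
  la <- lambda_log_acceptance(lambda_star, lambda, length(psi_j),
                              sum(log(psi_j)), gamma_inv2,
                              a_tilde, b_tilde, c)
  if (!is.finite(la)) {
    warning("non-finite MH log acceptance; proposal rejected", call. = FALSE)
    return(list(lambda = lambda, accepted = FALSE))
  }
  if (log(runif(1)) < la) {
    list(lambda = lambda_star, accepted = TRUE)
  } else {
    list(lambda = lambda, accepted = FALSE)
  }
}

#' Adjust the MH random-walk scale toward the target acceptance band
#'
#' Multiplicative tuning applied during burn-in only: the scale is increased
#' when the windowed acceptance rate is above the band (steps too timid) and
#' decreased when below. After burn-in the scale is frozen so the remaining
#' chain is a valid Markov chain.
#'
#' @param tuning_sigma current scale.
#' @param acc_rate acceptance rate over the last window.
#' @param lower,upper target band (defaults 0.20 and 0.30).
#' @param f_up,f_down multiplicative factors.
#' @return Updated scale.
#' @export
tune_mh <- function(tuning_sigma, acc_rate, lower = 0.20, upper = 0.30,
                    f_up = 1.25, f_down = 0.80) {
  if (acc_rate > upper) tuning_sigma * f_up
  else if (acc_rate < lower) tuning_sigma * f_down
  else tuning_sigma
}

# ridge-stabilized least-squares coefficients (plain OLS when well posed)
ls_coefficients <- function(X, y) {
  p <- ncol(X); n <- nrow(X)
  if (p < n) {
    fit <- lm.fit(X, y)
    if (fit$rank == p) return(unname(fit$coefficients))
  }
  XtX <- crossprod(X)
  ridge <- 1e-3 * mean(diag(XtX))
  diag(XtX) <- diag(XtX) + ridge
  drop(solve(XtX, crossprod(X, y)))
}

#' Initialize the sampler state
#'
#' The initial coefficient vector is the frequentist lasso estimate with a
#' single cross-validated penalty; the initial error variance is that fit's
#' mean squared residual; every \eqn{\lambda_j}, \eqn{\psi_{j,i}} and
#' \eqn{\gamma_j^{-2}} starts at 1. The data-driven hyperparameter
#' \eqn{\tilde b} is the mean of the squared (ridge-stabilized) least-squares
#' coefficients.
#'
#' @param X predictor matrix (columns standardized upstream).
#' @param y centered response.
#' @param groups platform index per column.
#' @param hyper an [ng_hyperparams()] object.
#' @return List: `beta`, `sigma2`, `psi`, `lambda`, `gamma_inv2`, `b_tilde`.
#' @export
initialize_state <- function(X, y, groups, hyper = ng_hyperparams()) {
  J <- max(groups)
  beta <- tryCatch({
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, intercept = FALSE,
                            standardize = FALSE, nfolds = 10)
    as.numeric(coef(cv, s = "lambda.min"))[-1]
  }, error = function(e) {
    warning("lasso initialization failed (", conditionMessage(e),
            "); starting from zero", call. = FALSE)
    rep(0, ncol(X))
  })
  sigma2 <- mean((y - drop(X %*% beta))^2)
  if (sigma2 <= 0) sigma2 <- var(y)
  b_tilde <- hyper$b_tilde
  if (is.null(b_tilde)) {
    b_tilde <- mean(ls_coefficients(X, y)^2)
    if (!is.finite(b_tilde) || b_tilde <= 0) b_tilde <- 1
  }
  list(beta = beta, sigma2 = sigma2, psi = rep(1, ncol(X)),
       lambda = rep(1, J), gamma_inv2 = rep(1, J), b_tilde = b_tilde)
}

# shared MCMC engine; prior = "ng" or "blasso"
run_shrinkage_mcmc <- function(X, y, groups, n_iter, burn_in, seed, hyper,
                               center_y, tuning_init, tune_window, prior,
                               global_lambda = FALSE, verbose = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y),
            length(groups) == ncol(X), n_iter > burn_in, burn_in >= 1)
  if (!is.null(seed)) set.seed(seed)
  groups <- as.integer(groups)
  J <- max(groups)
  p <- ncol(X); n <- nrow(X)
  y_center <- if (center_y) mean(y) else 0
  yc <- y - y_center
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, yc))

  st <- initialize_state(X, yc, groups, hyper)
  b_tilde <- st$b_tilde
  beta <- st$beta; sigma2 <- st$sigma2; psi <- st$psi
  lambda <- st$lambda; gamma_inv2 <- st$gamma_inv2

  S <- n_iter - burn_in
  draws_beta <- matrix(NA_real_, S, p)
  draws_sigma2 <- numeric(S)
  draws_lambda <- matrix(NA_real_, S, J)
  draws_gamma <- if (prior == "ng") matrix(NA_real_, S, J) else NULL
  tuning <- rep(tuning_init, J)
  tuning_trace <- list()
  acc_window <- rep(0, J); acc_post <- rep(0, J)
  win_count <- 0
  p_j <- tabulate(groups, nbins = J)

  for (it in seq_len(n_iter)) {
    beta <- update_beta(XtX, Xty, sigma2, psi)
    resid <- yc - drop(X %*% beta)
    sigma2 <- update_sigma2(resid, hyper$a, hyper$b)

    if (prior == "ng") {
      psi <- update_psi(beta, lambda, gamma_inv2, groups)
      gamma_inv2 <- update_gamma_inv2(psi, lambda, groups,
                                      hyper$a_tilde, b_tilde)
      for (j in seq_len(J)) {
        up <- update_lambda(lambda[j], psi[groups == j], gamma_inv2[j],
                            tuning[j], hyper$a_tilde, b_tilde, hyper$c)
        lambda[j] <- up$lambda
        acc_window[j] <- acc_window[j] + up$accepted
        if (it > burn_in) acc_post[j] <- acc_post[j] + up$accepted
      }
      win_count <- win_count + 1
      if (it <= burn_in && win_count == tune_window) {
        for (j in seq_len(J)) {
          tuning[j] <- tune_mh(tuning[j], acc_window[j] / tune_window)
        }
        tuning_trace[[length(tuning_trace) + 1L]] <- tuning
        acc_window[] <- 0; win_count <- 0
      } else if (win_count == tune_window) {
        acc_window[] <- 0; win_count <- 0
      }
    } else {  # Bayesian lasso: psi ~ Exp(lambda_j), conjugate gamma rate
      psi <- rgig(p, lambda = 0.5, chi = pmax(beta^2, 1e-12),
                  psi = 2 * lambda[groups])
      if (global_lambda) {
        lam <- rgamma(1, shape = p + 1, rate = 1 + sum(psi))
        lambda <- rep(lam, J)
      } else {
        sum_psi <- vapply(seq_len(J), function(j) sum(psi[groups == j]),
                          numeric(1))
        lambda <- rgamma(J, shape = p_j + 1, rate = 1 + sum_psi)
      }
    }

    if (!all(is.finite(beta)) || !is.finite(sigma2)) {
      stop("sampler diverged (non-finite state) at iteration ", it)
    }
    if (it > burn_in) {
      s <- it - burn_in
      draws_beta[s, ] <- beta
      draws_sigma2[s] <- sigma2
      draws_lambda[s, ] <- lambda
      if (prior == "ng") draws_gamma[s, ] <- gamma_inv2
    }
    if (verbose && it %% 1000 == 0) {
      message("iteration ", it, " / ", n_iter, " (sigma2 = ",
              signif(sigma2, 3), ")")
    }
  }
  colnames(draws_beta) <- colnames(X)
  structure(list(
    beta = draws_beta,
    sigma2 = draws_sigma2,
    lambda = draws_lambda,
    gamma_inv2 = draws_gamma,
    accept_rate = if (prior == "ng") acc_post / S else NULL,
    tuning = if (prior == "ng") tuning else NULL,
    tuning_trace = if (prior == "ng") do.call(rbind, tuning_trace) else NULL,
    n_iter = n_iter, burn_in = burn_in, seed = seed,
    hyper = hyper, b_tilde = b_tilde,
    groups = groups, y_center = y_center,
    method = if (prior == "ng") "normal-gamma" else "bayesian-lasso"
  ), class = "ng_chain")
}

#' Fit the clinical model by Gibbs sampling under the Normal-Gamma prior
#'
#' Runs the full MCMC: systematic-scan updates of \eqn{\beta} (multivariate
#' normal), \eqn{\sigma^2} (inverse gamma), \eqn{\psi} (generalized inverse
#' Gaussian), \eqn{\gamma_j^{-2}} (gamma) and each \eqn{\lambda_j}
#' (Metropolis-Hastings on the log scale with burn-in auto-tuning toward a
#' 20-30% acceptance rate). The response is centered by default (the model
#' carries no intercept).
#'
#' @param X predictor matrix (standardized columns).
#' @param y response (log survival).
#' @param groups integer platform label (1..J) per column of `X`.
#' @param n_iter total iterations (default 10000).
#' @param burn_in burn-in iterations discarded (default 500).
#' @param seed integer seed for exact reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @param hyper an [ng_hyperparams()] object.
#' @param center_y center the response before sampling (default `TRUE`).
#' @param tuning_init initial MH random-walk scale.
#' @param tune_window iterations per tuning adjustment during burn-in.
#' @param verbose print progress every 1000 iterations.
#' @return Object of class `ng_chain` with post-burn-in draws of `beta`
#'   (matrix S x p), `sigma2`, `lambda`, `gamma_inv2`, per-platform MH
#'   acceptance rates, frozen tuning scales and all settings.
#' @seealso [blasso_regress()], [tidy.ng_chain()], [glance.ng_chain()]
#' @export
ng_regress <- function(X, y, groups, n_iter = 10000, burn_in = 500,
                       seed = NULL, hyper = ng_hyperparams(),
                       center_y = TRUE, tuning_init = 1, tune_window = 50,
                       verbose = FALSE) {
  run_shrinkage_mcmc(X, y, groups, n_iter, burn_in, seed, hyper, center_y,
                     tuning_init, tune_window, prior = "ng",
                     verbose = verbose)
}

#' Fit the clinical model under the Bayesian lasso (comparator)
#'
#' Same scan structure as [ng_regress()] but with the double-exponential
#' hierarchy: \eqn{\beta_{j,i}|\psi_{j,i} \sim N(0, \psi_{j,i})},
#' \eqn{\psi_{j,i} \sim Exp(\lambda_j)}. The \eqn{\psi} conditional is
#' generalized inverse Gaussian with shape exponent 1/2; each platform rate
#' \eqn{\lambda_j} gets a conjugate Gamma(1, 1) prior and a closed-form gamma
#' update (set `global_lambda = TRUE` for a single shared rate).
#'
#' @inheritParams ng_regress
#' @param global_lambda use one shared exponential rate across platforms.
#' @return An `ng_chain` object (method `"bayesian-lasso"`).
#' @export
blasso_regress <- function(X, y, groups, n_iter = 10000, burn_in = 500,
                           seed = NULL, hyper = ng_hyperparams(),
                           center_y = TRUE, global_lambda = FALSE,
                           verbose = FALSE) {
  run_shrinkage_mcmc(X, y, groups, n_iter, burn_in, seed, hyper, center_y,
                     tuning_init = 1, tune_window = 50, prior = "blasso",
                     global_lambda = global_lambda, verbose = verbose)
}

#' Fit the Normal-Gamma clinical model to a clinical design
#'
#' Convenience wrapper of [ng_regress()] for a `clinical_design` built by
#' [build_clinical_design()]; the design's column annotation travels with the
#' chain so selection reports can be gene-annotated.
#'
#' @param design a `clinical_design`.
#' @param ... passed to [ng_regress()].
#' @return An `ng_chain` with an `annotation` element.
#' @export
run_ng_mcmc <- function(design, ...) {
  stopifnot(inherits(design, "clinical_design"))
  chain <- ng_regress(design$X, design$y, design$groups, ...)
  chain$annotation <- design$annotation
  chain$scale <- design$scale
  chain
}

#' Fit the Bayesian-lasso clinical model to a clinical design
#'
#' @param design a `clinical_design`.
#' @param ... passed to [blasso_regress()].
#' @return An `ng_chain` with an `annotation` element.
#' @export
run_blasso_mcmc <- function(design, ...) {
  stopifnot(inherits(design, "clinical_design"))
  chain <- blasso_regress(design$X, design$y, design$groups, ...)
  chain$annotation <- design$annotation
  chain$scale <- design$scale
  chain
}

#' @export
print.ng_chain <- function(x, ...) {
  cat("<ng_chain> ", x$method, ": ", nrow(x$beta), " stored draws (",
      x$n_iter, " iterations, ", x$burn_in, " burn-in), p = ",
      ncol(x$beta), "\n", sep = "")
  cat("  posterior mean sigma2: ", signif(mean(x$sigma2), 4), "\n", sep = "")
  if (!is.null(x$accept_rate)) {
    cat("  MH acceptance by platform: ",
        paste(signif(x$accept_rate, 3), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Posterior coefficient estimates
#'
#' @param object an `ng_chain`.
#' @param ... unused.
#' @return Named vector of posterior means.
#' @export
coef.ng_chain <- function(object, ...) colMeans(object$beta)

#' Posterior-mean predictions
#'
#' @param object an `ng_chain`.
#' @param newdata predictor matrix on the same scale the chain was fit on.
#' @param ... unused.
#' @return Numeric vector of predictions (response centering restored).
#' @export
predict.ng_chain <- function(object, newdata, ...) {
  drop(newdata %*% coef(object)) + object$y_center
}

#' Summarize a chain's coefficients
#'
#' Per-coefficient posterior mean, standard deviation and equal-tailed
#' credible intervals at each requested level, from the stored post-burn-in
#' draws.
#'
#' @param chain an `ng_chain`.
#' @param levels credibility levels (default 0.95 and 0.90).
#' @return Tibble with columns `term`, `estimate`, `std.error` and
#'   `conf.low.<level>` / `conf.high.<level>` per level, plus attribute
#'   `sigma2_mean`.
#' @export
summarize_chain <- function(chain, levels = c(0.95, 0.90)) {
  stopifnot(inherits(chain, "ng_chain"), all(levels > 0 & levels < 1))
  out <- tibble::tibble(
    term = colnames(chain$beta) %||% paste0("b", seq_len(ncol(chain$beta))),
    estimate = unname(colMeans(chain$beta)),
    std.error = unname(apply(chain$beta, 2, sd))
  )
  for (lv in levels) {
    qs <- apply(chain$beta, 2, quantile, probs = c((1 - lv) / 2, (1 + lv) / 2))
    tag <- sub("^0\\.", "", format(lv))
    out[[paste0("conf.low.", tag)]] <- unname(qs[1, ])
    out[[paste0("conf.high.", tag)]] <- unname(qs[2, ])
  }
  attr(out, "sigma2_mean") <- mean(chain$sigma2)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a fitted chain (broom-style)
#'
#' @param x an `ng_chain`.
#' @param conf.level single credibility level for the interval columns.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`; gene/platform annotation columns are joined when the chain
#'   was fit through [run_ng_mcmc()].
#' @method tidy ng_chain
#' @export
tidy.ng_chain <- function(x, conf.level = 0.95, ...) {
  s <- summarize_chain(x, levels = conf.level)
  names(s)[4:5] <- c("conf.low", "conf.high")
  if (!is.null(x$annotation)) {
    s <- dplyr::left_join(dplyr::rename(s, column = "term"),
                          x$annotation, by = "column")
    s <- dplyr::rename(s, term = "column")
  }
  s
}

#' One-row chain summary (broom-style)
#'
#' @param x an `ng_chain`.
#' @param ... unused.
#' @return Tibble with the posterior mean error variance, iteration counts
#'   and the mean MH acceptance rate (NA for the Bayesian lasso, which has no
#'   MH step).
#' @method glance ng_chain
#' @export
glance.ng_chain <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    sigma2_mean = mean(x$sigma2),
    n_iter = x$n_iter,
    burn_in = x$burn_in,
    n_draws = nrow(x$beta),
    mh_acceptance = if (is.null(x$accept_rate)) NA_real_
                    else mean(x$accept_rate)
  )
}

#' Trace / density plot of chain draws
#'
#' @param object an `ng_chain`.
#' @param pars parameter names to show (default: `sigma2` plus the first
#'   three coefficients).
#' @param ... unused.
#' @return A ggplot object (trace panels).
#' @method autoplot ng_chain
#' @export
autoplot.ng_chain <- function(object, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- c("sigma2", head(colnames(object$beta), 3))
  }
  dat <- purrr::map_dfr(pars, function(pp) {
    v <- if (pp == "sigma2") object$sigma2 else object$beta[, pp]
    tibble::tibble(parameter = pp, iteration = seq_along(v), value = v)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored iteration", y = "draw") +
    ggplot2::theme_bw()
}
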