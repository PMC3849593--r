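#' Ordinary least squares baseline
#'
#' Plain least-squares fit of the clinical model (no intercept by default:
#' the model as written has none and the response is centered upstream).
#' The error-variance estimate uses the maximum-likelihood denominator `n`
#' by default; classical t confidence intervals are returned at the
#' requested levels.
#'
#' @param X predictor matrix, `n > p` required.
#' @param y response vector.
#' @param levels confidence levels for the intervals.
#' @param ml_sigma2 if `TRUE` (default) divide the residual sum of squares by
#'   `n`; otherwise by `n - p`.
#' @param intercept include an intercept column (default `FALSE`).
#' @return Object of class `method_result`: `method`, `beta`, `sigma2`,
#'   `intercept`, and `intervals` (a named list of p x 2 matrices keyed by
#'   level).
#' @export
fit_least_squares <- function(X, y, levels = c(0.95, 0.90),
                              ml_sigma2 = TRUE, intercept = FALSE) {
  n <- nrow(X); p <- ncol(X)
  Xf <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  if (n <= ncol(Xf)) stop("least squares requires n > p")
  fit <- lm.fit(Xf, y)
  if (fit$rank < ncol(Xf)) stop("rank-deficient design; OLS baseline unavailable")
  beta_all <- fit$coefficients
  resid <- y - drop(Xf %*% beta_all)
  rss <- sum(resid^2)
  df <- n - ncol(Xf)
  sigma2 <- if (ml_sigma2) rss / n else rss / df
  XtXinv <- chol2inv(chol(crossprod(Xf)))
  se_all <- sqrt(diag(XtXinv) * rss / df)  # classical (unbiased) SEs
  idx <- if (intercept) -1 else seq_len(p)
  beta <- beta_all[idx]; se <- se_all[idx]
  intervals <- lapply(levels, function(lv) {
    tq <- qt((1 + lv) / 2, df)
    cbind(lower = beta - tq * se, upper = beta + tq * se)
  })
  names(intervals) <- format(levels)
  structure(list(method = "least squares", beta = unname(beta),
                 sigma2 = sigma2,
                 intercept = if (intercept) beta_all[1] else 0,
                 intervals = intervals),
            class = "method_result")
}

fit_glmnet_baseline <- function(X, y, alpha, rule, nfolds, intercept,
                                method_name) {
  rule <- match.arg(rule, c("one_se", "min"))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nfolds,
                          intercept = intercept)
  s <- if (rule == "one_se") "lambda.1se" else "lambda.min"
  co <- as.numeric(coef(cv, s = s))
  resid <- y - co[1] - drop(X %*% co[-1])
  structure(list(method = method_name, beta = co[-1],
                 sigma2 = mean(resid^2),
                 intercept = co[1],
                 intervals = NULL,
                 lambda = cv[[s]],
                 lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se),
            class = "method_result")
}

#' Frequentist lasso baseline
#'
#' Cross-validated L1-penalized least squares. The penalty is either the
#' cross-validation minimizer (`"min"`) or the largest penalty with CV error
#' within one standard error of the minimum (`"one_se"`). No coefficient
#' intervals are available (standard errors are undefined for coefficients
#' set to zero).
#'
#' @param X predictor matrix.
#' @param y response.
#' @param rule `"one_se"` or `"min"`.
#' @param nfolds CV folds (default 10); fold assignment follows the current
#'   RNG state, so seed upstream for reproducibility.
#' @param intercept include an intercept (default `FALSE`, matching the
#'   no-intercept clinical model).
#' @return A `method_result`.
#' @export
fit_l1 <- function(X, y, rule = c("one_se", "min"), nfolds = 10,
                   intercept = FALSE) {
  rule <- match.arg(rule)
  fit_glmnet_baseline(X, y, alpha = 1, rule, nfolds, intercept,
                      paste0("freq. lasso (", sub("one_se", "1 SE", rule), ")"))
}

#' Frequentist elastic-net baseline
#'
#' As [fit_l1()] with a mixed L1/L2 penalty; the mixing parameter defaults to
#' 0.5 (equal mixture).
#'
#' @inheritParams fit_l1
#' @param mixing elastic-net mixing parameter in (0, 1].
#' @return A `method_result`.
#' @export
fit_elastic_net <- function(X, y, mixing = 0.5, rule = c("one_se", "min"),
                            nfolds = 10, intercept = FALSE) {
  rule <- match.arg(rule)
  fit_glmnet_baseline(X, y, alpha = mixing, rule, nfolds, intercept,
                      paste0("freq. EN (", sub("one_se", "1 SE", rule), ")"))
}

#' Convert a posterior chain to a point-estimate method result
#'
#' Posterior means become the coefficient estimates; equal-tailed credible
#' intervals become the interval set; the error variance is the posterior
#' mean of sigma-squared.
#'
#' @param chain an `ng_chain`.
#' @param levels interval levels.
#' @return A `method_result`.
#' @export
as_method_result <- function(chain, levels = c(0.95, 0.90)) {
  stopifnot(inherits(chain, "ng_chain"))
  intervals <- lapply(levels, function(lv) {
    qs <- apply(chain$beta, 2, quantile, probs = c((1 - lv) / 2, (1 + lv) / 2))
    cbind(lower = qs[1, ], upper = qs[2, ])
  })
  names(intervals) <- format(levels)
  structure(list(
    method = if (chain$method == "normal-gamma") "NG (our method)"
             else "Bayesian lasso",
    beta = unname(colMeans(chain$beta)),
    sigma2 = mean(chain$sigma2),
    intercept = chain$y_center,
    intervals = intervals
  ), class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result> ", x$method, ": p = ", length(x$beta),
      ", sigma2_hat = ", signif(x$sigma2, 4), "\n", sep = "")
  invisible(x)
}

#' @export
predict.method_result <- function(object, newdata, ...) {
  drop(newdata %*% object$beta) + object$intercept
}

#' Interval coverage of the true coefficients
#'
#' Fraction of true coefficients lying inside their interval (closed
#' endpoints).
#'
#' @param intervals p x 2 matrix of lower/upper limits.
#' @param truth vector of true coefficients (length p).
#' @return Fraction in \[0, 1\].
#' @export
coverage <- function(intervals, truth) {
  stopifnot(is.matrix(intervals), ncol(intervals) == 2,
            nrow(intervals) == length(truth),
            all(intervals[, 1] <= intervals[, 2]))
  mean(truth >= intervals[, 1] & truth <= intervals[, 2])
}

#' Prediction mean-squared-error ratio against least squares
#'
#' Mean squared prediction error of the reference (least squares) divided by
#' that of the method, both evaluated on the same data; values above 1 mean
#' the method predicts better than least squares.
#'
#' @param reference a `method_result` (the least-squares fit).
#' @param method a `method_result` fitted on the same training data.
#' @param X_eval,y_eval evaluation data (training or test split).
#' @return Positive scalar.
#' @export
mse_ratio <- function(reference, method, X_eval, y_eval) {
  mse_ref <- mean((y_eval - predict(reference, X_eval))^2)
  mse_m <- mean((y_eval - predict(method, X_eval))^2)
  if (mse_m == 0) stop("method has zero evaluation MSE; ratio undefined")
  mse_ref / mse_m
}

#' Evaluate all methods on one simulated train/test pair
#'
#' Fits the Normal-Gamma sampler, least squares, the Bayesian lasso and the
#' cross-validated frequentist lasso / elastic net (both penalty rules) on
#' the training split, then reports each method's error-variance estimate,
#' 95% and 90% interval coverage of the true coefficients (NA where the
#' method provides no intervals) and training/test prediction-MSE ratios
#' against least squares.
#'
#' @param train list with elements `X`, `y`.
#' @param test list with elements `X`, `y`.
#' @param truth true coefficient vector.
#' @param groups platform index per column.
#' @param n_iter,burn_in MCMC settings for the Bayesian methods.
#' @param seed integer seed controlling the MCMC and CV fold randomness.
#' @param methods character subset of `c("ng", "ols", "blasso", "lasso",
#'   "enet")` (default all).
#' @return Tibble with one row per fitted method: `method`, `sigma2_hat`,
#'   `coverage_95`, `coverage_90`, `mse_ratio_train`, `mse_ratio_test`.
#' @export
evaluate_all <- function(train, test, truth, groups = NULL,
                         n_iter = 10000, burn_in = 500, seed = NULL,
                         methods = c("ng", "ols", "blasso", "lasso",
                                     "enet")) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- rep(1L, ncol(train$X))
  fits <- list()
  ols <- fit_least_squares(train$X, train$y)
  if ("ng" %in% methods) {
    fits[["ng"]] <- as_method_result(
      ng_regress(train$X, train$y, groups, n_iter = n_iter,
                 burn_in = burn_in))
  }
  if ("ols" %in% methods) fits[["ols"]] <- ols
  if ("blasso" %in% methods) {
    fits[["blasso"]] <- as_method_result(
      blasso_regress(train$X, train$y, groups, n_iter = n_iter,
                     burn_in = burn_in))
  }
  if ("lasso" %in% methods) {
    fits[["lasso_1se"]] <- fit_l1(train$X, train$y, rule = "one_se")
    fits[["lasso_min"]] <- fit_l1(train$X, train$y, rule = "min")
  }
  if ("enet" %in% methods) {
    fits[["enet_1se"]] <- fit_elastic_net(train$X, train$y, rule = "one_se")
    fits[["enet_min"]] <- fit_elastic_net(train$X, train$y, rule = "min")
  }
  purrr::map_dfr(fits, function(f) {
    cov95 <- if (!is.null(f$intervals)) coverage(f$intervals[[1]], truth)
             else NA_real_
    cov90 <- if (!is.null(f$intervals) && length(f$intervals) >= 2)
               coverage(f$intervals[[2]], truth) else NA_real_
    tibble::tibble(
      method = f$method,
      sigma2_hat = f$sigma2,
      coverage_95 = cov95,
      coverage_90 = cov90,
      mse_ratio_train = mse_ratio(ols, f, train$X, train$y),
      mse_ratio_test = mse_ratio(ols, f, test$X, test$y)
    )
  })
}
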