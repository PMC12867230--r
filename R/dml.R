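#' Configuration for double machine learning
#'
#' @param n_folds number of cross-fitting folds (>= 2; default 4).
#' @param learner nuisance learner: `"glmnet"` (penalized linear, default),
#'   `"ranger"` (random forest) or `"xgboost"` (gradient boosting).
#' @param seed seed controlling the fold permutation and any learner
#'   randomness; fixed seed gives deterministic estimates.
#' @param params named list of learner hyperparameters (held fixed for
#'   determinism). Defaults: glmnet `lambda = 0.01, alpha = 1`; ranger
#'   `num.trees = 300, min.node.size = 10`; xgboost `nrounds = 150,
#'   max_depth = 3, eta = 0.1`.
#' @return a `dml_config` list.
#' @export
dml_config <- function(n_folds = 4L, learner = c("glmnet", "ranger", "xgboost"),
                       seed = 1L, params = list()) {
  learner <- match.arg(learner)
  stopifnot(n_folds >= 2)
  defaults <- switch(learner,
    glmnet = list(lambda = 0.01, alpha = 1),
    ranger = list(num.trees = 300, min.node.size = 10),
    xgboost = list(nrounds = 150, max_depth = 3, eta = 0.1))
  structure(list(n_folds = as.integer(n_folds), learner = learner,
                 seed = as.integer(seed),
                 params = utils::modifyList(defaults, params)),
            class = "dml_config")
}

# Fit the configured learner on (X, y) and return a prediction closure.
fit_learner <- function(X, y, config) {
  p <- config$params
  switch(config$learner,
    glmnet = {
      fit <- glmnet::glmnet(X, y, alpha = p$alpha, lambda = p$lambda,
                            family = "gaussian", standardize = TRUE)
      function(Xn) as.numeric(stats::predict(fit, Xn))
    },
    ranger = {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop("learner 'ranger' requires the ranger package", call. = FALSE)
      }
      df <- as.data.frame(X); df$.y <- y
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = p$num.trees,
                            min.node.size = p$min.node.size,
                            seed = config$seed, num.threads = 1)
      function(Xn) stats::predict(fit, as.data.frame(Xn))$predictions
    },
    xgboost = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("learner 'xgboost' requires the xgboost package", call. = FALSE)
      }
      fit <- xgboost::xgb.train(
        params = list(max_depth = p$max_depth, eta = p$eta,
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = p$nrounds)
      function(Xn) stats::predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1))
    })
}

# Cross-fitted out-of-fold predictions of y on X.
crossfit_predict <- function(X, y, folds, config) {
  out <- numeric(length(y))
  for (k in sort(unique(folds))) {
    te <- folds == k
    pred <- fit_learner(X[!te, , drop = FALSE], y[!te], config)
    out[te] <- pred(X[te, , drop = FALSE])
  }
  out
}

make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Double machine learning for the partially linear model
#'
#' Estimates the treatment coefficient `theta` in
#' `Y = theta * P + g(X) + U`, `P = m(X) + V`, by K-fold cross-fitting:
#' nuisance regressions of the outcome and the treatment on the controls are
#' fit on each fold's complement, and `theta` solves the Robinson
#' residual-on-residual (partialling-out) moment on the held-out residuals.
#' The standard error comes from the influence-function variance. A binary
#' outcome is handled on the linear-probability scale, so `theta` is itself
#' the average treatment effect.
#'
#' @param data data frame.
#' @param outcome,treatment,controls column names (controls nonempty).
#' @param config a [dml_config()].
#' @param nuisance optional list with numeric vectors `lhat` (fitted
#'   `E[Y|X]`) and `mhat` (fitted `E[P|X]`) that replace the cross-fitted
#'   nuisances — the oracle limit of the estimator, used for verification.
#' @return a `dml_result`: `theta`, `se`, per-fold estimates, fold sizes and
#'   nuisance R-squareds.
#' @export
crossfit_plm <- function(data, outcome, treatment, controls,
                         config = dml_config(), nuisance = NULL) {
  stopifnot(length(controls) > 0)
  y <- as.numeric(data[[outcome]])
  p <- as.numeric(data[[treatment]])
  X <- build_design(data, controls, intercept = FALSE)
  folds <- make_folds(length(y), config$n_folds, config$seed)
  lhat <- nuisance$lhat %||% crossfit_predict(X, y, folds, config)
  mhat <- nuisance$mhat %||% crossfit_predict(X, p, folds, config)
  v <- p - mhat
  u <- y - lhat
  per_fold <- vapply(sort(unique(folds)), function(k) {
    i <- folds == k
    if (sum(v[i]^2) < 1e-12) {
      stop("fold ", k, " has (near-)constant residualized treatment; ",
           "re-split with a different seed", call. = FALSE)
    }
    sum(v[i] * u[i]) / sum(v[i]^2)
  }, numeric(1))
  theta <- sum(v * u) / sum(v^2)
  psi <- v * (u - theta * v)
  J <- mean(v^2)
  se <- sqrt(mean(psi^2) / J^2 / length(y))
  structure(list(
    theta = theta, se = se, per_fold = per_fold,
    n_obs = length(y), n_folds = config$n_folds, learner = config$learner,
    r2_outcome = 1 - stats::var(u) / stats::var(y),
    r2_treatment = 1 - stats::var(v) / stats::var(p),
    model = "partially_linear"), class = "dml_result")
}

#' Double machine learning for the partially linear IV model
#'
#' As [crossfit_plm()] but with a single continuous instrument: outcome,
#' treatment and instrument are all residualized on the controls by
#' cross-fitting, and `theta` comes from the instrumental moment on the
#' residuals, `theta = sum(z_res * y_res) / sum(z_res * p_res)`. A
#' first-stage residual covariance with |t| below 2 raises a
#' weak-instrument error.
#'
#' @param data data frame.
#' @param outcome,treatment,iv,controls column names.
#' @param config a [dml_config()].
#' @return a `dml_result`.
#' @export
crossfit_plm_iv <- function(data, outcome, treatment, iv, controls,
                            config = dml_config()) {
  stopifnot(length(controls) > 0)
  y <- as.numeric(data[[outcome]])
  p <- as.numeric(data[[treatment]])
  z <- as.numeric(data[[iv]])
  X <- build_design(data, controls, intercept = FALSE)
  folds <- make_folds(length(y), config$n_folds, config$seed)
  u <- y - crossfit_predict(X, y, folds, config)
  v <- p - crossfit_predict(X, p, folds, config)
  w <- z - crossfit_predict(X, z, folds, config)
  cov_wp <- mean(w * v)
  t_first <- cov_wp / (stats::sd(w * v) / sqrt(length(y)))
  if (!is.finite(t_first) || abs(t_first) < 2) {
    stop("weak instrument: residualized IV-treatment covariance t = ",
         sprintf("%.2f", t_first), call. = FALSE)
  }
  theta <- sum(w * u) / sum(w * v)
  psi <- w * (u - theta * v)
  J <- mean(w * v)
  se <- sqrt(mean(psi^2) / J^2 / length(y))
  per_fold <- vapply(sort(unique(folds)), function(k) {
    i <- folds == k
    sum(w[i] * u[i]) / sum(w[i] * v[i])
  }, numeric(1))
  structure(list(
    theta = theta, se = se, per_fold = per_fold,
    n_obs = length(y), n_folds = config$n_folds, learner = config$learner,
    first_stage_t = t_first,
    model = "partially_linear_iv"), class = "dml_result")
}

#' @export
print.dml_result <- function(x, ...) {
  cat(sprintf("<dml_result: %s, %s, %d folds>\n", x$model, x$learner, x$n_folds))
  cat(sprintf("  theta = %.4f (se %.4f), n = %d\n", x$theta, x$se, x$n_obs))
  cat("  per-fold:", sprintf("%.4f", x$per_fold), "\n")
  invisible(x)
}
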