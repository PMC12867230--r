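# Design-matrix construction shared by all estimators: factors and character
# columns become dummy columns with the most frequent level as reference.
build_design <- function(data, covariates, intercept = TRUE) {
  if (length(covariates) == 0) {
    return(if (intercept) matrix(1, nrow(data), 1,
                                 dimnames = list(NULL, "(Intercept)"))
           else matrix(0, nrow(data), 0))
  }
  df <- as.data.frame(data[covariates])
  for (cn in names(df)) {
    if (is.character(df[[cn]]) || is.factor(df[[cn]])) {
      f <- as.factor(df[[cn]])
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      df[[cn]] <- stats::relevel(f, ref = ref)
    }
  }
  fml <- if (intercept) ~ . else ~ . - 1
  stats::model.matrix(fml, df)
}

#' Fit a probit model by maximum likelihood
#'
#' Single-equation probit of a binary outcome on covariates, via
#' `stats::glm` with a probit link. Collinear columns are dropped with a
#' warning; perfect separation is an error.
#'
#' @param data a data frame.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate columns (factors become
#'   dummies with the most frequent level as reference).
#' @return a `tp_fit` object: coefficient table, log-likelihood, n.
#' @export
fit_probit <- function(data, outcome, covariates) {
  y <- data[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  X <- build_design(data, covariates)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(link = "probit")))
  eta <- stats::qnorm(pmin(pmax(fit$fitted.values, 1e-300), 1 - 1e-16))
  if (length(unique(y)) == 2 &&
      (min(eta[y == 1]) > max(eta[y == 0]) ||
         max(eta[y == 1]) < min(eta[y == 0]))) {
    stop("perfect separation: the linear predictor fully classifies the outcome",
         call. = FALSE)
  }
  aliased <- is.na(fit$coefficients)
  if (any(aliased)) {
    warning("rank-deficient design; dropped: ",
            paste(names(fit$coefficients)[aliased], collapse = ", "),
            call. = FALSE)
    X <- X[, !aliased, drop = FALSE]
    fit <- stats::glm.fit(X, y, family = stats::binomial(link = "probit"))
  }
  cf <- fit$coefficients
  # observed-information SEs from the final IWLS weights
  XtWX <- crossprod(X * sqrt(fit$weights))
  se <- sqrt(diag(solve(XtWX)))
  ll <- sum(stats::dbinom(y, 1, pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12),
                          log = TRUE))
  new_tp_fit(
    coefficients = tibble::tibble(
      equation = "outcome", term = names(cf), estimate = unname(cf),
      se = unname(se), z = unname(cf / se),
      p_value = 2 * stats::pnorm(-abs(unname(cf / se)))),
    log_likelihood = ll, n_obs = length(y), model = "probit",
    converged = fit$converged,
    fitted = fit$fitted.values, design = X)
}

new_tp_fit <- function(coefficients, log_likelihood, n_obs, model,
                       converged = TRUE, treatment_coefficient = NA_real_,
                       ate = NA_real_, rho = NA_real_, rho_se = NA_real_,
                       ...) {
  structure(list(coefficients = coefficients,
                 treatment_coefficient = treatment_coefficient, ate = ate,
                 rho = rho, rho_se = rho_se,
                 log_likelihood = log_likelihood, n_obs = n_obs,
                 model = model, converged = converged, ...),
            class = "tp_fit")
}

#' @export
print.tp_fit <- function(x, ...) {
  cat(sprintf("<tp_fit: %s>  n = %d, logLik = %.1f%s\n", x$model, x$n_obs,
              x$log_likelihood,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (!is.na(x$treatment_coefficient)) {
    cat(sprintf("  treatment coefficient: %.4f   ATE: %.4f\n",
                x$treatment_coefficient, x$ate))
  }
  if (!is.na(x$rho)) cat(sprintf("  rho: %.4f (se %.4f)\n", x$rho, x$rho_se))
  print(x$coefficients, n = 20)
  invisible(x)
}

# Predicted probability from a coefficient vector and design matrix.
probit_prob <- function(X, beta) stats::pnorm(as.numeric(X %*% beta))
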