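#' Probit with a binary treatment, exogenous or endogenous
#'
#' The central estimator: a two-equation probit in which a binary treatment
#' (the targeted-placement indicator) enters a binary outcome (one-year
#' patient-and-graft survival), allowing the treatment to be endogenous.
#'
#' * Treatment equation: `T = 1[w'alpha + xi > 0]`, where `w` holds the
#'   treatment drivers (recipient age, donor KDPI, recipient EPTS).
#' * Outcome equation: `Y = 1[x'beta + beta1 T + eps > 0]`, with controls `x`.
#' * `(xi, eps)` bivariate standard normal with correlation `rho`.
#'
#' `mode = "exogenous"` fits a single probit of the outcome on the actual
#' treatment plus controls (valid only if `rho = 0`). `mode = "endogenous"`
#' estimates the joint model: by default full-information maximum likelihood
#' over both equations with bivariate-normal likelihood contributions
#' (`method = "fiml"`), or a two-step control-function variant that inserts
#' the treatment equation's generalized residual into the outcome probit
#' (`method = "twostep"`). FIML reports `rho` with a Wald test of
#' `rho = 0`, and the average treatment effect on the probability scale,
#' `ATE = mean[pnorm(x'beta + beta1) - pnorm(x'beta)]`.
#'
#' @param data a data frame.
#' @param outcome,treatment names of the binary outcome/treatment columns.
#' @param step1_covariates drivers of the treatment equation.
#' @param controls control columns of the outcome equation (factors become
#'   fixed-effect dummies, reference = most frequent level).
#' @param mode `"endogenous"` (default) or `"exogenous"`.
#' @param method `"fiml"` (default) or `"twostep"` for the endogenous mode.
#' @return a `tp_fit` with both equations' coefficients, `rho`, and `ate`.
#' @export
fit_treatment_probit <- function(data, outcome, treatment,
                                 step1_covariates, controls = character(),
                                 mode = c("endogenous", "exogenous"),
                                 method = c("fiml", "twostep")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  y <- data[[outcome]]
  tr <- data[[treatment]]
  stopifnot(all(y %in% c(0, 1)), all(tr %in% c(0, 1)))

  if (mode == "exogenous") {
    fit <- fit_probit(data, outcome, c(treatment, controls))
    cf <- fit$coefficients
    b1 <- cf$estimate[cf$term == treatment]
    X <- fit$design
    tcol <- which(colnames(X) == treatment)
    X1 <- X; X1[, tcol] <- 1
    X0 <- X; X0[, tcol] <- 0
    beta <- cf$estimate
    fit$treatment_coefficient <- b1
    fit$ate <- mean(probit_prob(X1, beta) - probit_prob(X0, beta))
    fit$model <- "probit_exogenous_treatment"
    return(fit)
  }

  W <- build_design(data, step1_covariates)
  s1 <- fit_probit(data, treatment, step1_covariates)
  Xc <- build_design(data, c(treatment, controls))

  if (method == "twostep") {
    a <- s1$coefficients$estimate
    wi <- as.numeric(W %*% a)
    lam <- stats::dnorm(wi) / pmax(stats::pnorm(wi), 1e-12)
    lam0 <- stats::dnorm(wi) / pmax(stats::pnorm(-wi), 1e-12)
    gres <- tr * lam - (1 - tr) * lam0
    d2 <- as.data.frame(data)
    d2$.gres <- gres
    fit <- fit_probit(d2, outcome, c(treatment, controls, ".gres"))
    cf <- fit$coefficients
    b1 <- cf$estimate[cf$term == treatment]
    X <- fit$design
    tcol <- which(colnames(X) == treatment)
    X1 <- X; X1[, tcol] <- 1
    X0 <- X; X0[, tcol] <- 0
    fit$coefficients <- dplyr::bind_rows(
      dplyr::mutate(s1$coefficients, equation = "treatment"), cf)
    fit$treatment_coefficient <- b1
    fit$ate <- mean(probit_prob(X1, cf$estimate) - probit_prob(X0, cf$estimate))
    fit$model <- "probit_endogenous_treatment_twostep"
    return(fit)
  }

  # ---- FIML ----
  ka <- ncol(W); kb <- ncol(Xc)
  st <- 2 * tr - 1
  sy <- 2 * y - 1
  tcol <- which(colnames(Xc) == treatment)

  nll <- function(par) {
    alpha <- par[seq_len(ka)]
    beta <- par[ka + seq_len(kb)]
    rho <- tanh(par[ka + kb + 1])
    a <- st * as.numeric(W %*% alpha)
    b <- sy * as.numeric(Xc %*% beta)
    r <- st * sy * rho
    -sum(log(pmax(pbinorm(a, b, r), 1e-300)))
  }
  grad <- function(par) {
    alpha <- par[seq_len(ka)]
    beta <- par[ka + seq_len(kb)]
    tau <- par[ka + kb + 1]
    rho <- tanh(tau)
    a <- st * as.numeric(W %*% alpha)
    b <- sy * as.numeric(Xc %*% beta)
    r <- st * sy * rho
    P <- pmax(pbinorm(a, b, r), 1e-300)
    s <- sqrt(1 - r^2)
    da <- stats::dnorm(a) * stats::pnorm((b - r * a) / s) / P
    db <- stats::dnorm(b) * stats::pnorm((a - r * b) / s) / P
    dr <- dbinorm(a, b, r) / P
    ga <- -colSums((da * st) * W)
    gb <- -colSums((db * sy) * Xc)
    gt <- -sum(dr * st * sy) * (1 - rho^2)
    c(ga, gb, gt)
  }

  # start from the separate single-equation probits, rho = 0
  start <- c(s1$coefficients$estimate, {
    f0 <- fit_probit(data, outcome, c(treatment, controls))
    cfn <- colnames(Xc)
    est <- stats::setNames(f0$coefficients$estimate, f0$coefficients$term)
    unname(est[cfn])
  }, 0)
  start[is.na(start)] <- 0

  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  H <- numDeriv::jacobian(grad, opt$par)
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(opt$par),
                                                     length(opt$par)))
  se <- sqrt(pmax(diag(V), 0))

  alpha <- opt$par[seq_len(ka)]
  beta <- opt$par[ka + seq_len(kb)]
  tau <- opt$par[ka + kb + 1]
  rho <- tanh(tau)
  rho_se <- (1 - rho^2) * se[ka + kb + 1]
  if (abs(rho) > 0.99) {
    warning("estimated error correlation is at the boundary (|rho| > 0.99)",
            call. = FALSE)
  }

  X1 <- Xc; X1[, tcol] <- 1
  X0 <- Xc; X0[, tcol] <- 0
  ate <- mean(probit_prob(X1, beta) - probit_prob(X0, beta))

  terms <- c(paste0("treat:", colnames(W)), colnames(Xc), "atanh_rho")
  eqs <- c(rep("treatment", ka), rep("outcome", kb), "correlation")
  est_all <- c(alpha, beta, tau)
  cf <- tibble::tibble(
    equation = eqs,
    term = c(colnames(W), colnames(Xc), "atanh_rho"),
    estimate = est_all, se = se, z = est_all / se,
    p_value = 2 * stats::pnorm(-abs(est_all / se)))

  new_tp_fit(
    coefficients = cf,
    treatment_coefficient = beta[tcol],
    ate = ate, rho = rho, rho_se = rho_se,
    log_likelihood = -opt$value, n_obs = length(y),
    model = "probit_endogenous_treatment_fiml",
    converged = opt$convergence == 0,
    rho_wald_p = 2 * stats::pnorm(-abs(tau / se[ka + kb + 1])),
    treatment_se = se[ka + tcol],
    design = Xc)
}
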