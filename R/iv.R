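#' Market-share instrument for targeted placement
#'
#' For each transplant program and calendar month, the instrument is the
#' program's share of its donation service area's transplant volume over the
#' previous three calendar months:
#' `IV = (program's transplants in months m-3..m-1) /
#'       (all transplants in the same DSA in months m-3..m-1)`.
#' It takes the same value for all transplants a program performs in a
#' month. Months with zero DSA volume in the window leave the instrument
#' undefined, and the first three months of the data window carry an
#' `excluded` flag since their windows are incomplete.
#'
#' @param transplants transplants tibble (`txp_id`, `transplant_date`).
#' @param program_dsa tibble mapping `txp_id` to `dsa_id`. Programs without
#'   DSA information are dropped with a warning.
#' @return tibble with `txp_id`, `month` ("YYYY-MM"), `iv_value` in `[0,1]`
#'   (NA when undefined) and `excluded` for the first three data months.
#' @export
compute_iv <- function(transplants, program_dsa) {
  tx <- transplants
  tx$dsa_id <- program_dsa$dsa_id[match(tx$txp_id, program_dsa$txp_id)]
  if (anyNA(tx$dsa_id)) {
    warning(sum(is.na(tx$dsa_id)), " transplant(s) without DSA information dropped",
            call. = FALSE)
    tx <- tx[!is.na(tx$dsa_id), ]
  }
  midx <- function(d) as.integer(format(d, "%Y")) * 12L +
    as.integer(format(d, "%m")) - 1L
  tx$m <- midx(tx$transplant_date)
  first_m <- min(tx$m)
  months <- seq(min(tx$m), max(tx$m))

  by_txp <- tx |> dplyr::count(.data$txp_id, .data$dsa_id, .data$m)
  grid <- tidyr::expand_grid(
    txp_id = unique(tx$txp_id), m = months)
  grid$dsa_id <- program_dsa$dsa_id[match(grid$txp_id, program_dsa$txp_id)]

  win_count <- function(keys, key, m) {
    # transplants of `key` in months m-3..m-1
    vapply(seq_along(key), function(i) {
      sum(keys$n[keys$k == key[i] & keys$m >= m[i] - 3 & keys$m <= m[i] - 1])
    }, numeric(1))
  }
  txp_counts <- by_txp |> dplyr::transmute(k = .data$txp_id, m = .data$m, n = .data$n)
  dsa_counts <- by_txp |>
    dplyr::group_by(k = .data$dsa_id, m = .data$m) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")

  num <- win_count(txp_counts, grid$txp_id, grid$m)
  den <- win_count(dsa_counts, grid$dsa_id, grid$m)
  tibble::tibble(
    txp_id = grid$txp_id,
    month = sprintf("%04d-%02d", grid$m %/% 12L, grid$m %% 12L + 1L),
    iv_value = ifelse(den > 0, num / den, NA_real_),
    excluded = grid$m < first_m + 3L
  )
}

#' Two-step instrumental-variable probit
#'
#' Step 1 regresses the (endogenous) binary treatment on the market-share
#' instrument by probit; step 2 regresses the outcome on the predicted
#' treatment probability plus controls. Before fitting, observations in the
#' first three data months and observations without a defined instrument
#' are dropped. The instrument's relevance (step-1 z) is checked, with a
#' weak-instrument warning below |z| = 2, and the exclusion diagnostic
#' refits the outcome probit with the instrument in place of the treatment.
#' Step-2 standard errors for the treatment coefficient come from a
#' nonparametric bootstrap over observations (the predicted treatment is a
#' generated regressor).
#'
#' @param data data frame of transplants with outcome, treatment, controls,
#'   `txp_id` and `transplant_date`.
#' @param outcome,treatment,controls column names.
#' @param iv an IV series from [compute_iv()].
#' @param step1_controls include the controls in step 1 as well (default
#'   instrument-only).
#' @param n_boot bootstrap replicates for the step-2 SE.
#' @param seed seed for the bootstrap resampling.
#' @return a `tp_fit` with the step-1 instrument coefficient, the step-2
#'   treatment coefficient with bootstrap SE, the ATE, a residual-correlation
#'   diagnostic, and the relevance/exclusion test results.
#' @export
fit_iv_probit <- function(data, outcome, treatment, controls = character(),
                          iv, step1_controls = FALSE, n_boot = 50L, seed = 1L) {
  d <- as.data.frame(data)
  d$month <- format(d$transplant_date, "%Y-%m")
  d <- dplyr::left_join(d, iv, by = c("txp_id", "month"))
  n0 <- nrow(d)
  d <- d[!d$excluded & !is.na(d$iv_value), ]
  if (nrow(d) < n0) {
    message(n0 - nrow(d),
            " observation(s) dropped (first 3 months or undefined instrument)")
  }
  s1_covs <- c("iv_value", if (step1_controls) controls)

  two_steps <- function(dd) {
    s1 <- fit_probit(dd, treatment, s1_covs)
    dd$.that <- s1$fitted
    s2 <- fit_probit(dd, outcome, c(".that", controls))
    list(s1 = s1, s2 = s2, dd = dd)
  }
  ts <- two_steps(d)
  s1 <- ts$s1; s2 <- ts$s2

  cf1 <- s1$coefficients
  z_iv <- cf1$z[cf1$term == "iv_value"]
  weak <- abs(z_iv) < 2
  if (weak) warning("weak instrument: step-1 |z| = ",
                    sprintf("%.2f", abs(z_iv)), " < 2", call. = FALSE)

  cf2 <- s2$coefficients
  theta <- cf2$estimate[cf2$term == ".that"]
  X <- s2$design
  tcol <- which(colnames(X) == ".that")
  X1 <- X; X1[, tcol] <- 1
  X0 <- X; X0[, tcol] <- 0
  ate <- mean(probit_prob(X1, cf2$estimate) - probit_prob(X0, cf2$estimate))

  # exclusion diagnostic: does the instrument shift survival directly?
  excl <- fit_probit(d, outcome, c("iv_value", controls))
  cfe <- excl$coefficients
  excl_p <- cfe$p_value[cfe$term == "iv_value"]

  # residual-correlation diagnostic between the two response residuals
  r1 <- d[[treatment]] - s1$fitted
  r2 <- d[[outcome]] - s2$fitted
  rho_diag <- stats::cor(r1, r2)

  boot_se <- NA_real_
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    th <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      tsb <- tryCatch(two_steps(d[idx, ]), error = function(e) NULL)
      if (is.null(tsb)) return(NA_real_)
      cb <- tsb$s2$coefficients
      cb$estimate[cb$term == ".that"]
    }, numeric(1))
    boot_se <- stats::sd(th, na.rm = TRUE)
  }

  cf <- dplyr::bind_rows(
    dplyr::mutate(cf1, equation = "treatment"),
    dplyr::mutate(cf2, equation = "outcome"))
  cf$se[cf$equation == "outcome" & cf$term == ".that"] <- boot_se
  cf$z[cf$equation == "outcome" & cf$term == ".that"] <- theta / boot_se
  cf$p_value[cf$equation == "outcome" & cf$term == ".that"] <-
    2 * stats::pnorm(-abs(theta / boot_se))

  new_tp_fit(
    coefficients = cf,
    treatment_coefficient = theta, ate = ate,
    rho = rho_diag, rho_se = NA_real_,
    log_likelihood = s2$log_likelihood, n_obs = nrow(d),
    model = "probit_iv_twostep", converged = TRUE,
    iv_coefficient = cf1$estimate[cf1$term == "iv_value"],
    iv_relevance_z = z_iv, weak_instrument = weak,
    exclusion_p = excl_p, treatment_se = boot_se)
}
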