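test_that("bivariate normal CDF matches mvtnorm and factorizes at rho = 0", {
  set.seed(50)
  a <- rnorm(40); b <- rnorm(40); r <- runif(40, -0.95, 0.95)
  ref <- mapply(function(x, y, z) {
    mvtnorm::pmvnorm(upper = c(x, y), corr = matrix(c(1, z, z, 1), 2))[1]
  }, a, b, r)
  expect_equal(pbinorm(a, b, r), ref, tolerance = 1e-9)
  expect_equal(pbinorm(a, b, 0), pnorm(a) * pnorm(b), tolerance = 1e-12)
  # monotone in rho for positive-quadrant limits
  expect_true(all(diff(pbinorm(rep(0.5, 5), 0.5, c(-0.8, -0.4, 0, 0.4, 0.8))) > 0))
})

test_that("intercept-only probit inverts the outcome rate", {
  d <- data.frame(y = rep(c(0, 1), each = 500))
  f <- fit_probit(d, "y", character())
  expect_equal(f$coefficients$estimate[1], 0, tolerance = 1e-6)
  d2 <- data.frame(y = rep(c(0, 1), c(250, 750)))
  f2 <- fit_probit(d2, "y", character())
  expect_equal(f2$coefficients$estimate[1], qnorm(0.75), tolerance = 1e-6)
})

test_that("probit recovers known coefficients and flags separation", {
  set.seed(51)
  n <- 20000
  x1 <- rnorm(n); x2 <- runif(n)
  y <- as.integer(0.5 + 0.8 * x1 - 1.2 * x2 + rnorm(n) > 0)
  f <- fit_probit(data.frame(y = y, x1 = x1, x2 = x2), "y", c("x1", "x2"))
  cf <- f$coefficients
  for (i in seq_len(3)) {
    expect_lt(abs(cf$estimate[i] - c(0.5, 0.8, -1.2)[i]), 2 * cf$se[i])
  }
  # perfect separation
  ds <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  expect_error(fit_probit(ds, "y", "x"), "separation")
})

test_that("rank-deficient designs drop columns with a warning", {
  set.seed(52)
  d <- data.frame(y = rbinom(200, 1, 0.5), x1 = rnorm(200))
  d$x2 <- 2 * d$x1
  expect_warning(f <- fit_probit(d, "y", c("x1", "x2")), "rank-deficient")
  expect_false("x2" %in% f$coefficients$term)
})

test_that("endogenous and exogenous fits agree when errors are uncorrelated", {
  d <- simulate_treatment_data(6000, tp_propensity = RECOVERY_PROPENSITY,
                               outcome_coeffs = recovery_coeffs(0.3),
                               rho = 0, seed = 53)
  exo <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                              mode = "exogenous")
  endo <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                               mode = "endogenous")
  expect_lt(abs(endo$treatment_coefficient - exo$treatment_coefficient),
            2 * endo$treatment_se)
  expect_lt(abs(endo$rho), 2 * endo$rho_se + 0.05)
  # joint likelihood at rho = 0 can be no worse than the factorized fits
  s1 <- fit_probit(d, "tp", STEP1_COVS)
  s2 <- fit_probit(d, "survival_1yr", c("tp", SURV_COVS))
  expect_gte(endo$log_likelihood + 1e-4,
             s1$log_likelihood + s2$log_likelihood)
})

test_that("confounding biases the exogenous fit; FIML corrects it", {
  d <- simulate_treatment_data(20000, tp_propensity = RECOVERY_PROPENSITY,
                               outcome_coeffs = recovery_coeffs(0),
                               rho = 0.5, seed = 54)
  exo <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                              mode = "exogenous")
  endo <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                               mode = "endogenous")
  cf <- exo$coefficients
  exo_se <- cf$se[cf$term == "tp"]
  expect_gt(exo$treatment_coefficient, 4 * exo_se)     # biased away from 0
  # single-draw check: FIML removes most of the bias (the formal 95%
  # coverage property over 20 replicate cohorts is asserted separately)
  expect_lt(abs(endo$treatment_coefficient), 3 * endo$treatment_se)
  expect_lt(abs(endo$treatment_coefficient),
            abs(exo$treatment_coefficient) / 2)
  expect_lt(abs(endo$rho - 0.5), 2.5 * endo$rho_se)
})

test_that("two-step control function moves the estimate toward the truth", {
  d <- simulate_treatment_data(8000, tp_propensity = RECOVERY_PROPENSITY,
                               outcome_coeffs = recovery_coeffs(0),
                               rho = 0.5, seed = 55)
  exo <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                              mode = "exogenous")
  ts <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                             mode = "endogenous", method = "twostep")
  expect_lt(abs(ts$treatment_coefficient), abs(exo$treatment_coefficient))
  expect_true(any(ts$coefficients$term == ".gres"))
})

test_that("estimates are invariant to row order and ATE to rescaling", {
  d <- simulate_treatment_data(4000, tp_propensity = RECOVERY_PROPENSITY,
                               outcome_coeffs = recovery_coeffs(0.3),
                               rho = 0.3, seed = 56)
  f1 <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                             mode = "endogenous")
  perm <- withr::with_seed(1, sample.int(nrow(d)))
  f2 <- fit_treatment_probit(d[perm, ], "survival_1yr", "tp", STEP1_COVS,
                             SURV_COVS, mode = "endogenous")
  expect_equal(f1$treatment_coefficient, f2$treatment_coefficient,
               tolerance = 1e-5)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-4)
  # affine rescaling of a continuous control: coefficient scales, ATE fixed
  d10 <- d; d10$age_at_listing <- d10$age_at_listing / 10
  g1 <- fit_treatment_probit(d, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                             mode = "exogenous")
  g2 <- fit_treatment_probit(d10, "survival_1yr", "tp", STEP1_COVS, SURV_COVS,
                             mode = "exogenous")
  c1 <- g1$coefficients; c2 <- g2$coefficients
  expect_equal(c2$estimate[c2$term == "age_at_listing"],
               10 * c1$estimate[c1$term == "age_at_listing"], tolerance = 1e-5)
  expect_equal(g1$ate, g2$ate, tolerance = 1e-7)
})

test_that("market-share instrument reproduces hand-computed ratios", {
  tx <- tibble::tibble(
    txp_id = c(rep("A", 3), "B", rep("A", 2), "B"),
    transplant_date = as.Date(c("2015-01-10", "2015-02-05", "2015-03-20",
                                "2015-02-14", "2015-04-02", "2015-04-20",
                                "2015-04-09")))
  pd <- tibble::tibble(txp_id = c("A", "B"), dsa_id = "D1")
  iv <- compute_iv(tx, pd)
  # April window = Jan..Mar: A performed 3 of 4 -> 0.75, B 1 of 4 -> 0.25
  expect_equal(iv$iv_value[iv$txp_id == "A" & iv$month == "2015-04"], 0.75)
  expect_equal(iv$iv_value[iv$txp_id == "B" & iv$month == "2015-04"], 0.25)
  # first three data months flagged excluded
  expect_true(all(iv$excluded[iv$month %in% c("2015-01", "2015-02", "2015-03")]))
  # single-program DSA: share is 1 wherever defined
  pd1 <- tibble::tibble(txp_id = c("A", "B"), dsa_id = c("D1", "D2"))
  iv1 <- compute_iv(tx, pd1)
  expect_true(all(iv1$iv_value[!is.na(iv1$iv_value)] == 1))
  # empty prior window leaves the instrument undefined
  expect_true(is.na(iv$iv_value[iv$month == "2015-01"][1]))
})

# synthetic IV design: treatment driven by the instrument, outcome unaffected
make_iv_data <- function(n_txp = 24, months = 15, seed = 57) {
  set.seed(seed)
  rows <- list()
  pd <- tibble::tibble(txp_id = sprintf("T%02d", seq_len(n_txp)),
                       dsa_id = sprintf("D%d", 1 + (seq_len(n_txp) - 1) %% 6))
  for (m in seq_len(months)) {
    for (tx in pd$txp_id) {
      k <- rpois(1, 2 + 6 * (match(tx, pd$txp_id) %% 4 == 0))
      if (k > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          txp_id = tx,
          transplant_date = as.Date("2015-01-15") + 30.44 * (m - 1) +
            sample(0:10, k, TRUE))
      }
    }
  }
  tx <- dplyr::bind_rows(rows)
  tx$transplant_date <- as.Date(tx$transplant_date)
  iv <- compute_iv(tx, pd)
  tx$month <- format(tx$transplant_date, "%Y-%m")
  tx <- dplyr::left_join(tx, iv, by = c("txp_id", "month"))
  tx <- tx[!is.na(tx$iv_value), ]
  n <- nrow(tx)
  tx$x1 <- rnorm(n)
  tx$tp <- as.integer(-1 + 3 * tx$iv_value + 0.3 * tx$x1 + rnorm(n) > 0)
  tx$survival_1yr <- as.integer(1.2 + 0.4 * tx$x1 + rnorm(n) > 0)  # no effect
  list(data = dplyr::select(tx, -"iv_value", -"excluded", -"month"), iv = iv)
}

test_that("IV probit recovers a null treatment effect with a relevant instrument", {
  md <- make_iv_data()
  f <- fit_iv_probit(md$data, "survival_1yr", "tp", "x1", md$iv,
                     n_boot = 40, seed = 1)
  expect_gt(abs(f$iv_relevance_z), 2)
  expect_false(f$weak_instrument)
  expect_lt(abs(f$treatment_coefficient), 2 * f$treatment_se)
  # generated-regressor SE exceeds the naive probit SE on the same data
  naive <- fit_probit(dplyr::mutate(md$data, month = format(transplant_date, "%Y-%m")) |>
                        dplyr::left_join(md$iv, by = c("txp_id", "month")) |>
                        dplyr::filter(!excluded & !is.na(iv_value)),
                      "survival_1yr", c("tp", "x1"))
  ncf <- naive$coefficients
  expect_gt(f$treatment_se, ncf$se[ncf$term == "tp"])
})

test_that("an irrelevant instrument raises a weak-instrument warning", {
  md <- make_iv_data(seed = 58)
  d <- md$data
  set.seed(58)
  d$tp <- rbinom(nrow(d), 1, 0.3)  # treatment ignores the instrument
  expect_warning(fit_iv_probit(d, "survival_1yr", "tp", "x1", md$iv,
                               n_boot = 0), "weak instrument")
})
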