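#' D'Agostino-Pearson omnibus normality test
#'
#' The skewness-kurtosis normality gate: combines the z-equivalents of
#' sample skewness and kurtosis into K2 = Z1^2 + Z2^2, referred to a
#' chi-square with 2 df. Requires n >= 8 for the kurtosis transformation to
#' be defined.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `statistic` (K2) and `p_value`.
#' @export
sk_normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) {
    stop("normality gate requires n >= 8 (got n = ", n, ")", call. = FALSE)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness z (D'Agostino 1970 transformation)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe-Glynn transformation)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

# Mann-Whitney U with normal approximation: tie-corrected variance and
# continuity correction; returns U (for the x sample), z and p.
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(statistic = u1, z = 0, p_value = 1))
  cc <- sign(u1 - mu) * 0.5
  z <- (u1 - mu - cc) / sqrt(sigma2)
  list(statistic = u1, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Compare a continuous variable across two groups
#'
#' Gated two-sample comparison: if both samples are consistent with
#' normality under the skewness-kurtosis test at `alpha`, an unpaired Welch
#' t-test (unequal variances) is used; otherwise the Mann-Whitney U test
#' with a tie- and continuity-corrected normal-approximation z statistic.
#'
#' @param x,y numeric samples, each of size >= 8.
#' @param alpha significance level of the normality gate.
#' @param variable optional variable name carried into the result.
#' @return a `comparison_result` tibble row: means, medians, test used,
#'   statistic, z (Mann-Whitney branch), p-value and the gate p-values.
#' @export
compare_continuous <- function(x, y, alpha = 0.05, variable = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  gx <- sk_normality_test(x); gy <- sk_normality_test(y)
  normal <- gx$p_value > alpha && gy$p_value > alpha
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- tibble::tibble(test = "welch_t", statistic = unname(tt$statistic),
                          z = NA_real_, p_value = tt$p.value)
  } else {
    mw <- mann_whitney_z(x, y)
    res <- tibble::tibble(test = "mann_whitney_u", statistic = mw$statistic,
                          z = mw$z, p_value = mw$p_value)
  }
  structure(tibble::tibble(
    variable = variable,
    mean_x = mean(x), mean_y = mean(y),
    median_x = stats::median(x), median_y = stats::median(y),
    res,
    effect_size = NA_real_,
    normality_p_x = gx$p_value, normality_p_y = gy$p_value
  ), class = c("comparison_result", "tbl_df", "tbl", "data.frame"))
}

#' Compare a categorical variable via chi-square and Cramer's V
#'
#' Pearson chi-square test of independence (no continuity correction) with
#' Cramer's V = sqrt(chi2 / (n * (min(r, c) - 1))) as the effect size.
#'
#' @param tab a contingency table (matrix of nonnegative counts, >= 2x2).
#' @param variable optional variable name.
#' @return a `comparison_result` tibble row with `statistic` (chi-square),
#'   `p_value` and `effect_size` (Cramer's V).
#' @export
compare_categorical <- function(tab, variable = NA_character_) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1)))
  structure(tibble::tibble(
    variable = variable, mean_x = NA_real_, mean_y = NA_real_,
    median_x = NA_real_, median_y = NA_real_,
    test = "chi_square", statistic = unname(ct$statistic), z = NA_real_,
    p_value = ct$p.value, effect_size = v,
    normality_p_x = NA_real_, normality_p_y = NA_real_
  ), class = c("comparison_result", "tbl_df", "tbl", "data.frame"))
}

#' Empirical-CDF stochastic dominance verdict
#'
#' Evaluates both empirical CDFs on the pooled support and reports whether
#' one sample is stochastically smaller than the other in the usual
#' first-order sense: `x <=st y` iff `P(Y <= t) <= P(X <= t)` for all t,
#' with weak inequality everywhere (tolerance 0). Identical eCDFs are
#' reported as `"equal"`; crossing eCDFs as `"neither"`.
#'
#' @param x,y nonempty numeric samples.
#' @return one of `"x_le_y"`, `"y_le_x"`, `"equal"`, `"neither"`.
#' @export
ecdf_dominance <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  x_le_y <- all(fy <= fx)  # y stochastically larger
  y_le_x <- all(fx <= fy)
  if (x_le_y && y_le_x) "equal"
  else if (x_le_y) "x_le_y"
  else if (y_le_x) "y_le_x"
  else "neither"
}

#' Test homogeneity of the targeting rate over a time stratum
#'
#' Chi-square test of homogeneity of the TP proportion across hours of the
#' day, weekdays, or calendar months, using each transplant's batch/response
#' timestamp (falling back to the transplant date for NTP rows when no
#' response time is available).
#'
#' @param labels a [label_cohort()] result.
#' @param cohort the labeled cohort (for offer timestamps).
#' @param stratum one of `"hour"`, `"weekday"`, `"month"`.
#' @return a `comparison_result` row (chi-square, p-value, Cramer's V).
#' @export
temporal_trend_test <- function(labels, cohort, stratum = c("hour", "weekday", "month")) {
  stratum <- match.arg(stratum)
  lb <- labels$labels
  of <- cohort$offers
  ts <- of$initial_response_time[match(paste(lb$donor_id, lb$ptr_id),
                                       paste(of$donor_id, of$ptr_id))]
  keep <- !is.na(ts)
  if (!any(keep)) stop("no transplant timestamps available", call. = FALSE)
  ts <- ts[keep]
  strat <- switch(stratum,
                  hour = format(ts, "%H", tz = "UTC"),
                  weekday = format(ts, "%u", tz = "UTC"),
                  month = format(ts, "%Y-%m", tz = "UTC"))
  is_tp <- lb$label[keep] == "TP"
  tab <- table(strat, factor(is_tp, levels = c(FALSE, TRUE)))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning(sum(empty), " empty stratum(s) dropped", call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2) {
    stop("temporal trend test undefined with a single stratum", call. = FALSE)
  }
  if (any(colSums(tab) == 0)) {
    stop("degenerate table: no variation in labels", call. = FALSE)
  }
  compare_categorical(tab, variable = paste0("tp_rate_by_", stratum))
}

#' Group-comparison summary tables for a labeled cohort
#'
#' Reproduces the descriptive methodology on the synthetic cohort: TP vs
#' NTP donors (KDPI, age, race, diabetes), TP vs NTP recipients (EPTS, age,
#' time to transplant, survival), and BTD vs non-BTD candidates (age and
#' waiting time at listing), each row carrying the gated continuous test or
#' the chi-square with Cramer's V.
#'
#' @param labels a [label_cohort()] result.
#' @param cohort the labeled cohort.
#' @return list of tibbles `donors`, `recipients`, `candidates`, plus
#'   `group_sizes`.
#' @export
cohort_summary <- function(labels, cohort) {
  cls <- classify_entities(labels, cohort)
  out <- list()

  d <- dplyr::inner_join(cohort$donors, cls$donors, by = "donor_id")
  tpd <- d[d$donor_class == "TP", ]; ntpd <- d[d$donor_class == "NTP", ]
  out$donors <- if (nrow(tpd) >= 8 && nrow(ntpd) >= 8) {
    dplyr::bind_rows(
      compare_continuous(ntpd$kdpi, tpd$kdpi, variable = "kdpi"),
      compare_continuous(ntpd$age, tpd$age, variable = "age"),
      compare_categorical(table(d$donor_class, d$race), variable = "race"),
      compare_categorical(table(d$donor_class, d$diabetes), variable = "diabetes"))
  } else tibble::tibble()

  tx <- cohort$transplants
  r <- tx |>
    dplyr::inner_join(cls$recipients, by = "ptr_id") |>
    dplyr::inner_join(dplyr::select(cohort$candidates, "ptr_id", "epts",
                                    "age_at_listing"), by = "ptr_id")
  tpr <- r[r$recipient_class == "TP", ]; ntpr <- r[r$recipient_class == "NTP", ]
  out$recipients <- if (nrow(tpr) >= 8 && nrow(ntpr) >= 8) {
    dplyr::bind_rows(
      compare_continuous(ntpr$epts, tpr$epts, variable = "epts"),
      compare_continuous(ntpr$age_at_listing, tpr$age_at_listing, variable = "age"),
      compare_continuous(ntpr$time_to_transplant, tpr$time_to_transplant,
                         variable = "time_to_transplant"),
      compare_categorical(table(r$recipient_class, r$survival_1yr),
                          variable = "survival_1yr"))
  } else tibble::tibble()

  cc <- dplyr::inner_join(cohort$candidates, cls$candidates, by = "ptr_id")
  btd <- cc[cc$btd_candidate, ]; nbtd <- cc[!cc$btd_candidate, ]
  out$candidates <- if (nrow(btd) >= 8 && nrow(nbtd) >= 8) {
    dplyr::bind_rows(
      compare_continuous(nbtd$age_at_listing, btd$age_at_listing, variable = "age"),
      compare_categorical(table(cc$btd_candidate, cc$sex), variable = "sex"))
  } else tibble::tibble()

  out$group_sizes <- tibble::tibble(
    group = c("tp_donors", "ntp_donors", "tp_recipients", "ntp_recipients",
              "btd_candidates", "non_btd_candidates"),
    n = c(nrow(tpd), nrow(ntpd), nrow(tpr), nrow(ntpr), nrow(btd), nrow(nbtd)))
  out
}

#' Count/percentage reporting arithmetic
#'
#' The single rounding convention used by every reported count/share pair:
#' `100 * count / total`, rounded to `digits` decimal places.
#'
#' @param count,total nonnegative counts, `total > 0`.
#' @param digits decimal places of the printed percentage.
#' @return the percentage as a number.
#' @export
count_share <- function(count, total, digits = 2) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
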