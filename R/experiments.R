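#' Build the transplant-level estimation table
#'
#' One row per transplant with the donor, recipient and match covariates,
#' the outcome, and the targeted-placement indicator from the labeling
#' engine — the table every estimator and experiment consumes.
#'
#' @param cohort a labeled [tp_cohort()].
#' @param labels the matching [label_cohort()] result.
#' @return a tibble with covariates, `tp` (0/1) and `survival_1yr`.
#' @export
estimation_table <- function(cohort, labels) {
  tx <- cohort$transplants
  lb <- labels$labels
  tx |>
    dplyr::inner_join(dplyr::select(cohort$donors, "donor_id", "kdpi",
                                    donor_age = "age"), by = "donor_id") |>
    dplyr::inner_join(dplyr::select(cohort$candidates, "ptr_id", "dsa_id",
                                    "epts", "age_at_listing", "listing_date"),
                      by = "ptr_id") |>
    dplyr::mutate(
      tp = as.integer(lb$label[match(paste(.data$donor_id, .data$ptr_id),
                                     paste(lb$donor_id, lb$ptr_id))] == "TP"),
      year = format(.data$transplant_date, "%Y"),
      month = format(.data$transplant_date, "%m"))
}

# Default representative covariate set of the latent survival equation.
SURVIVAL_COVARIATES <- c("kdpi", "age_at_listing", "epts",
                         "time_to_transplant", "cit_hours")

#' In-silico counterfactual for targeted-placement recipients
#'
#' What if targeted recipients had instead waited and received a kidney like
#' their non-targeted counterparts? A survival probit without the treatment
#' indicator is fit to the recipients' data; each TP recipient is matched to
#' NTP recipients at (i) the same program, (ii) the same EPTS vigintile
#' (20 equal-probability bins of the pooled recipient EPTS distribution)
#' and (iii) longer waiting time; and the recipient's predicted survival is
#' re-evaluated substituting the matched set's average KDPI and average
#' waiting time. Recipients without matches are excluded from the paired
#' comparison and counted.
#'
#' @param est an [estimation_table()].
#' @param covariates survival-equation covariates (must contain `kdpi` and
#'   `time_to_transplant`).
#' @param ntp_only fit the survival equation on NTP recipients only instead
#'   of all recipients.
#' @param fit optionally, a frozen `tp_fit` from a previous run; predictions
#'   then reuse its coefficients exactly.
#' @return a `counterfactual_tp` result: per-recipient predictions, means,
#'   and a paired t-test p-value.
#' @export
counterfactual_tp <- function(est, covariates = SURVIVAL_COVARIATES,
                              ntp_only = FALSE, fit = NULL) {
  stopifnot(all(c("kdpi", "time_to_transplant") %in% covariates))
  if (is.null(fit)) {
    fit_data <- if (ntp_only) est[est$tp == 0, ] else est
    fit <- fit_probit(fit_data, "survival_1yr", covariates)
  }
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)

  qs <- stats::quantile(est$epts, probs = seq(0, 1, by = 0.05))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  est$epts_bin <- cut(est$epts, breaks = unique(qs), labels = FALSE)

  predict_p <- function(df) {
    X <- build_design(df, covariates)
    probit_prob(X[, names(beta), drop = FALSE], beta)
  }

  tp_rows <- which(est$tp == 1)
  res <- lapply(tp_rows, function(i) {
    m <- est$tp == 0 & est$txp_id == est$txp_id[i] &
      est$epts_bin == est$epts_bin[i] &
      est$time_to_transplant > est$time_to_transplant[i]
    nm <- sum(m)
    cur <- predict_p(est[i, ])
    if (nm == 0) {
      return(tibble::tibble(ptr_id = est$ptr_id[i], n_matches = 0L,
                            current = cur, counterfactual = NA_real_))
    }
    cf_row <- est[i, ]
    cf_row$kdpi <- mean(est$kdpi[m])
    cf_row$time_to_transplant <- mean(est$time_to_transplant[m])
    tibble::tibble(ptr_id = est$ptr_id[i], n_matches = nm,
                   current = cur, counterfactual = predict_p(cf_row))
  })
  per <- dplyr::bind_rows(res)
  matched <- per[!is.na(per$counterfactual), ]
  pval <- if (nrow(matched) >= 2 &&
                stats::sd(matched$current - matched$counterfactual) > 0) {
    stats::t.test(matched$current, matched$counterfactual, paired = TRUE)$p.value
  } else if (nrow(matched) >= 1) 1 else NA_real_
  structure(list(
    per_recipient = per,
    n_tp = length(tp_rows), n_matched = nrow(matched),
    n_unmatched = sum(per$n_matches == 0),
    mean_current = mean(matched$current),
    mean_counterfactual = mean(matched$counterfactual),
    p_value = pval, fit = fit), class = "counterfactual_tp")
}

#' @export
print.counterfactual_tp <- function(x, ...) {
  cat(sprintf("<counterfactual_tp> %d TP recipients, %d matched (%d unmatched)\n",
              x$n_tp, x$n_matched, x$n_unmatched))
  cat(sprintf("  mean predicted survival: current %.4f vs counterfactual %.4f (paired p = %.4f)\n",
              x$mean_current, x$mean_counterfactual, x$p_value))
  invisible(x)
}

#' Missed-opportunity counting for batch-turn-down recipients
#'
#' For recipients who were skipped in at least one batch turn down before
#' their transplant, counts how many had at least one earlier skipped offer
#' whose estimated survival probability — substituting that donor's KDPI
#' and the waiting time implied by the offer date — is at least as high as
#' the estimated survival of the transplant they eventually received (ties
#' count). The survival equation is a probit with a BTD-exposure indicator
#' fit on all recipients. Lead time is months (30.44 days) from the
#' earliest such offer to the actual transplant.
#'
#' @param cohort a labeled [tp_cohort()].
#' @param labels the [label_cohort()] result.
#' @param exclusion_mode `"none"` or `"refusal_801_and_other"` (drop skipped
#'   offers declined with code 801 or a free-text/"other" reason before
#'   counting).
#' @param covariates survival-equation covariates.
#' @param fit optional frozen `tp_fit` whose coefficients are reused.
#' @return a `missed_opportunity` result.
#' @export
missed_opportunity_btd <- function(cohort, labels,
                                   exclusion_mode = c("none", "refusal_801_and_other"),
                                   covariates = SURVIVAL_COVARIATES,
                                   fit = NULL) {
  exclusion_mode <- match.arg(exclusion_mode)
  est <- estimation_table(cohort, labels)
  cls <- classify_entities(labels, cohort)
  est$btd <- as.integer(est$ptr_id %in%
                          cls$recipients$ptr_id[cls$recipients$btd_recipient])
  if (is.null(fit)) {
    fit <- fit_probit(est, "survival_1yr", c("btd", covariates))
  }
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  predict_p <- function(df) {
    X <- build_design(df, c("btd", covariates))
    probit_prob(X[, names(beta), drop = FALSE], beta)
  }

  mem <- labels$btd_members |>
    dplyr::inner_join(dplyr::select(cohort$offers, "match_run_id", "ptr_id",
                                    "refusal_code", "initial_response_time"),
                      by = c("match_run_id", "ptr_id")) |>
    dplyr::inner_join(dplyr::select(cohort$donors, "donor_id",
                                    offer_kdpi = "kdpi"), by = "donor_id")
  if (exclusion_mode == "refusal_801_and_other") {
    rc <- mem$refusal_code
    drop <- !is.na(rc) & (rc == "801" | !grepl("^[0-9]+$", rc))
    mem <- mem[!drop, ]
  }

  btd_rec <- est[est$btd == 1, ]
  out <- lapply(seq_len(nrow(btd_rec)), function(i) {
    r <- btd_rec[i, ]
    mi <- mem[mem$ptr_id == r$ptr_id &
                as.Date(mem$batch_time, tz = "UTC") < r$transplant_date, ]
    accepted_p <- predict_p(r)
    if (nrow(mi) == 0) {
      return(tibble::tibble(ptr_id = r$ptr_id, n_earlier_offers = 0L,
                            accepted_p = accepted_p, best_offer_p = NA_real_,
                            dominated = FALSE, lead_months = NA_real_))
    }
    offer_date <- as.Date(mi$initial_response_time, tz = "UTC")
    hyp <- r[rep(1, nrow(mi)), ]
    hyp$kdpi <- mi$offer_kdpi
    hyp$time_to_transplant <-
      as.numeric(offer_date - r$listing_date) / 365.25
    offer_p <- predict_p(hyp)
    dom <- offer_p >= accepted_p
    lead <- if (any(dom)) {
      as.numeric(r$transplant_date - min(offer_date[dom])) / DAYS_PER_MONTH
    } else NA_real_
    tibble::tibble(ptr_id = r$ptr_id, n_earlier_offers = nrow(mi),
                   accepted_p = accepted_p, best_offer_p = max(offer_p),
                   dominated = any(dom), lead_months = lead)
  })
  per <- dplyr::bind_rows(out)
  n_btd <- nrow(btd_rec)
  n_dom <- sum(per$dominated)
  structure(list(
    per_recipient = per,
    n_btd_recipients = n_btd,
    n_with_dominating_offer = n_dom,
    share_pct = if (n_btd) count_share(n_dom, n_btd, 1) else NA_real_,
    mean_lead_months = mean(per$lead_months, na.rm = TRUE),
    exclusion_mode = exclusion_mode, fit = fit), class = "missed_opportunity")
}

#' @export
print.missed_opportunity <- function(x, ...) {
  cat(sprintf("<missed_opportunity> %d / %d BTD recipients (%.1f%%) had >= 1 dominating earlier offer\n",
              x$n_with_dominating_offer, x$n_btd_recipients, x$share_pct))
  cat(sprintf("  mean lead time of earliest dominating offer: %.1f months\n",
              x$mean_lead_months))
  invisible(x)
}

#' Placebo test: random pseudo-treatment relabeling
#'
#' Draws, per replicate, a uniform random sample of transplants of the same
#' size as the true targeted-placement count, relabels them as pseudo-TP,
#' and refits the exogenous and endogenous treatment models. Under the
#' null the pseudo-treatment coefficient should be nonsignificant and the
#' treatment-equation covariates uninformative.
#'
#' @param est an [estimation_table()] (or any data frame with the treatment
#'   column and covariates).
#' @param outcome,treatment,step1_covariates,controls model columns as in
#'   [fit_treatment_probit()].
#' @param n_replicates number of pseudo-TP samples (default 5).
#' @param seed master seed; replicate seeds are derived from it.
#' @param alpha significance level for the summary.
#' @param models which treatment models to refit per replicate; the
#'   significance summary always uses the exogenous coefficient.
#' @return a `placebo_result` with one row per replicate.
#' @export
placebo_test <- function(est, outcome = "survival_1yr", treatment = "tp",
                         step1_covariates = c("age_at_listing", "kdpi", "epts"),
                         controls = c("kdpi", "age_at_listing", "epts",
                                      "cit_hours"),
                         n_replicates = 5L, seed = 1L, alpha = 0.05,
                         models = c("exogenous", "endogenous")) {
  models <- match.arg(models, several.ok = TRUE)
  n_tp <- sum(est[[treatment]] == 1)
  if (n_tp == 0) stop("placebo test undefined: zero treated observations",
                      call. = FALSE)
  rows <- lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed, paste0("placebo", r))
    set.seed(rs)
    idx <- sample.int(nrow(est), n_tp)
    d <- as.data.frame(est)
    d$.pseudo_tp <- 0L
    d$.pseudo_tp[idx] <- 1L
    exo <- fit_treatment_probit(d, outcome, ".pseudo_tp",
                                step1_covariates, controls, mode = "exogenous")
    cfx <- exo$coefficients
    p_exo <- cfx$p_value[cfx$term == ".pseudo_tp"]
    if ("endogenous" %in% models) {
      endo <- fit_treatment_probit(d, outcome, ".pseudo_tp",
                                   step1_covariates, controls,
                                   mode = "endogenous", method = "fiml")
      cfe <- endo$coefficients
      p_endo <- cfe$p_value[cfe$equation == "outcome" & cfe$term == ".pseudo_tp"]
      coef_endo <- endo$treatment_coefficient
      rho_endo <- endo$rho
    } else {
      p_endo <- NA_real_; coef_endo <- NA_real_; rho_endo <- NA_real_
    }
    tibble::tibble(
      replicate = r, seed = rs, n_pseudo = n_tp,
      coef_exogenous = exo$treatment_coefficient, p_exogenous = p_exo,
      coef_endogenous = coef_endo, p_endogenous = p_endo,
      rho = rho_endo,
      significant = p_exo < alpha)
  })
  tab <- dplyr::bind_rows(rows)
  structure(list(replicates = tab, n_tp = n_tp, alpha = alpha,
                 n_significant = sum(tab$significant)),
            class = "placebo_result")
}

#' @export
print.placebo_result <- function(x, ...) {
  cat(sprintf("<placebo_result> %d replicates of %d pseudo-TP transplants\n",
              nrow(x$replicates), x$n_tp))
  cat(sprintf("  exogenous pseudo-treatment significant at %.2f in %d/%d replicates\n",
              x$alpha, x$n_significant, nrow(x$replicates)))
  print(x$replicates)
  invisible(x)
}
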