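#' Configuration for the synthetic match-run generator
#'
#' The generator emulates the structure of national kidney match-run extracts:
#' per-donor priority-ordered candidate lists, per-program response batches
#' with shared timestamps, a targeted-placement (TP) propensity driven by
#' recipient age, donor KDPI and recipient EPTS, and one-year patient-and-
#' graft survival generated from a latent probit with configurable treatment
#' effect and error correlation.
#'
#' The treatment process is a threshold-crossing probit: a transplant pair is
#' targeted when `a0 + a_age*age + a_kdpi*KDPI + a_epts*EPTS + xi > 0`, and
#' survival is `1[b0 + b1*TP + covariates + eps > 0]`, with `(xi, eps)`
#' bivariate standard normal with correlation `rho`. Defaults for the
#' propensity slopes are the magnitudes typical of observed targeted
#' utilization (age 0.026 per year, KDPI 0.395, EPTS -0.613), with the
#' intercept set so roughly 7% of transplants are targeted; the outcome
#' intercept is set so marginal one-year survival is about 94%.
#'
#' @param n_donors,n_candidates,n_txps,n_dsas registry sizes.
#' @param date_range two dates bounding donor arrivals.
#' @param tp_propensity named vector `(intercept, age, kdpi, epts)` for the
#'   treatment equation.
#' @param outcome_coeffs named vector `(intercept, tp, kdpi, age, epts, cit)`
#'   for the latent survival equation.
#' @param rho error correlation in `(-1, 1)` between treatment and outcome
#'   disturbances (treatment endogeneity).
#' @param kdpi_mean,epts_mean configured marginal means of donor KDPI and
#'   candidate EPTS.
#' @param btd_sizes,btd_size_probs distribution over generated batch sizes
#'   (number of skipped higher-ranked candidates).
#' @param rule_mix probabilities over the three targeting response patterns.
#' @param jitter_sd timestamp jitter (standard deviation, minutes) applied to
#'   batch member initial-response times; 0 gives noiseless batches.
#' @param p_bypass,p_pediatric_donor,p_pediatric_candidate,p_dual,p_multi_organ,p_open_offer
#'   injection rates for records the preparation chain must remove.
#' @param p_refusal_801,p_freetext share of declines coded 801 / free text.
#' @param p_stale_z share of in-sequence acceptances whose terminal response
#'   is left as a stale provisional yes ("Z") for the normalization step to
#'   reinterpret.
#' @param cit_mean_tp,cit_mean_ntp,cit_sd cold-ischemia-time distribution (hours).
#' @param seed integer seed; a fixed seed makes the whole cohort deterministic.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_donors = 2000,
                       n_candidates = 12000,
                       n_txps = 40,
                       n_dsas = 12,
                       date_range = as.Date(c("2015-01-01", "2018-12-31")),
                       tp_propensity = c(intercept = -2.70, age = 0.026,
                                         kdpi = 0.395, epts = -0.613),
                       outcome_coeffs = c(intercept = 2.8, tp = 0,
                                          kdpi = -0.8, age = -0.01,
                                          epts = -0.6, cit = -0.005),
                       rho = -0.05,
                       kdpi_mean = 0.43,
                       epts_mean = 0.50,
                       btd_sizes = 4:8,
                       btd_size_probs = c(0.45, 0.25, 0.15, 0.10, 0.05),
                       rule_mix = c(0.145, 0.078, 0.777),
                       jitter_sd = 0,
                       p_bypass = 0.02,
                       p_pediatric_donor = 0.02,
                       p_pediatric_candidate = 0.02,
                       p_dual = 0.01,
                       p_multi_organ = 0.01,
                       p_open_offer = 0.01,
                       p_refusal_801 = 0.10,
                       p_freetext = 0.03,
                       p_stale_z = 0.02,
                       cit_mean_tp = 20,
                       cit_mean_ntp = 16.3,
                       cit_sd = 5,
                       seed = 1L) {
  stopifnot(abs(rho) < 1, n_donors >= 0, n_candidates >= 0,
            n_txps >= 1, n_dsas >= 1,
            length(btd_sizes) == length(btd_size_probs),
            length(rule_mix) == 3, all(rule_mix >= 0))
  cfg <- as.list(environment())
  cfg$date_range <- as.Date(date_range)
  cfg$rule_mix <- rule_mix / sum(rule_mix)
  cfg$btd_size_probs <- btd_size_probs / sum(btd_size_probs)
  structure(cfg, class = "sim_config")
}

#' Simulate the donor, candidate and program registries
#'
#' Donor KDPI and candidate EPTS are probit-transformed latent scores with a
#' positive loading on age, so older donors have stochastically higher KDPI;
#' the configured marginal means hold exactly in expectation. Each candidate
#' is assigned to one transplant program and each program to one donation
#' service area (DSA). Listing dates fall up to three years before the study
#' window opens so waiting times at transplant are realistic.
#'
#' @param config a [sim_config()].
#' @return list with `donors`, `candidates`, `programs` tibbles.
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "registry"))
  nd <- config$n_donors
  nc <- config$n_candidates

  # probit latent with var 1 split between an age loading and noise; the
  # shift qnorm(mean)*sqrt(2) makes E[pnorm(shift + latent)] = mean exactly
  z_age_d <- stats::rnorm(nd)
  donor_age <- pmin(pmax(40 + 15 * z_age_d, 18), 80)
  ped_d <- stats::runif(nd) < config$p_pediatric_donor
  donor_age[ped_d] <- stats::runif(sum(ped_d), 1, 17)
  kdpi <- stats::pnorm(stats::qnorm(config$kdpi_mean) * sqrt(2) +
                         0.8 * z_age_d + 0.6 * stats::rnorm(nd))
  donors <- tibble::tibble(
    donor_id = sprintf("D%05d", seq_len(nd)),
    kdpi = kdpi,
    age = donor_age,
    race = sample(c("White", "Black", "Hispanic", "Other"), nd, TRUE,
                  prob = c(0.62, 0.16, 0.15, 0.07)),
    diabetes = as.integer(stats::runif(nd) < 0.08 + 0.2 * kdpi),
    creatinine = round(exp(stats::rnorm(nd, log(1.0), 0.45)), 2),
    cause_of_death = sample(c("Anoxia", "Stroke", "HeadTrauma", "Other"),
                            nd, TRUE, prob = c(0.42, 0.25, 0.26, 0.07))
  )

  programs <- tibble::tibble(
    txp_id = sprintf("T%03d", seq_len(config$n_txps)),
    dsa_id = sprintf("DSA%02d", 1 + (seq_len(config$n_txps) - 1) %% config$n_dsas)
  )
  # unequal program volumes: a few high-volume centers dominate
  txp_w <- stats::rexp(config$n_txps) + 0.2

  z_age_c <- stats::rnorm(nc)
  cand_age <- pmin(pmax(52 + 13 * z_age_c, 18), 85)
  ped_c <- stats::runif(nc) < config$p_pediatric_candidate
  cand_age[ped_c] <- stats::runif(sum(ped_c), 5, 17)
  epts <- stats::pnorm(stats::qnorm(config$epts_mean) * sqrt(2) +
                         0.8 * z_age_c + 0.6 * stats::rnorm(nc))
  start <- config$date_range[1]
  candidates <- tibble::tibble(
    ptr_id = sprintf("P%06d", seq_len(nc)),
    txp_id = sample(programs$txp_id, nc, TRUE, prob = txp_w),
    epts = epts,
    age_at_listing = cand_age,
    sex = sample(c("M", "F"), nc, TRUE, prob = c(0.6, 0.4)),
    race = sample(c("White", "Black", "Hispanic", "Other"), nc, TRUE,
                  prob = c(0.45, 0.30, 0.17, 0.08)),
    listing_date = start - 365 * 3 +
      as.integer(stats::runif(nc, 0,
        as.numeric(config$date_range[2] - start) + 365 * 3))
  )
  candidates$dsa_id <- programs$dsa_id[match(candidates$txp_id, programs$txp_id)]
  candidates <- candidates[c("ptr_id", "txp_id", "dsa_id", "epts",
                             "age_at_listing", "sex", "race", "listing_date")]
  list(donors = donors, candidates = candidates, programs = programs)
}

# sample() without the scalar-x pitfall: draws n elements of x itself.
sample_idx <- function(x, n) x[sample.int(length(x), n)]

# Draw the (xi, eps) disturbance pair: bivariate standard normal, corr rho.
draw_errors <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(xi = z1, eps = z2)
}

#' Simulate match runs with timestamped responses and ground truth
#'
#' For each donor kidney a recipient is drawn from one program's waiting
#' candidates, the treatment disturbance decides whether the pair is a
#' targeted placement, and the match run is built accordingly: a targeted
#' pair gets a batch of identical-code, identical-timestamp declines for
#' higher-ranked same-program candidates and an acceptance at or before the
#' batch time, following one of the three response patterns; a non-targeted
#' pair is accepted near the top of the list with strictly distinct decline
#' timestamps above it. Bypass-resolved runs, pediatric pairs, dual and
#' multi-organ transplants, open offers and refusal codes (801 / free text)
#' are injected at configured rates for testing the preparation chain.
#'
#' @param registry output of [simulate_registry()].
#' @param config a [sim_config()].
#' @return list with `offers`, `transplants_skeleton` (pair, date, flags,
#'   latent disturbances, true TP flag) and `truth` (a `ground_truth` list
#'   with per-transplant true flags, per-offer batch memberships and the
#'   generating parameters).
#' @export
simulate_match_runs <- function(registry, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "matchruns"))
  don <- registry$donors
  cand <- registry$candidates
  nd <- nrow(don)
  if (nd == 0) {
    return(list(offers = empty_offers(), transplants_skeleton = NULL,
                truth = empty_truth(config)))
  }

  cand_by_txp <- split(seq_len(nrow(cand)), cand$txp_id)
  txp_ids <- names(cand_by_txp)
  txp_w <- vapply(cand_by_txp, length, 1L)
  transplanted_before <- rep(as.Date(NA), nrow(cand)) # date candidate left list

  start <- config$date_range[1]
  span_days <- as.numeric(config$date_range[2] - start)
  offer_dates <- start + sort(as.integer(stats::runif(nd, 0, span_days)))
  offer_mins <- as.integer(stats::runif(nd, 0, 24 * 60))

  errs <- draw_errors(nd, config$rho)
  a <- config$tp_propensity

  offers_list <- vector("list", nd)
  tx_list <- vector("list", nd)
  btd_list <- vector("list", nd)
  warned <- FALSE

  for (i in seq_len(nd)) {
    run_id <- sprintf("MR%05d", i)
    odate <- offer_dates[i]
    t_r <- floor_minute(as.POSIXct(paste(odate, "00:00"), tz = "UTC") +
                          offer_mins[i] * 60)
    # recipient: a waiting candidate of one program
    txp <- sample(txp_ids, 1, prob = txp_w)
    pool <- cand_by_txp[[txp]]
    avail <- pool[cand$listing_date[pool] < odate &
                    (is.na(transplanted_before[pool]) |
                       transplanted_before[pool] > odate)]
    if (length(avail) < 2) next
    rec <- sample_idx(avail, 1)

    tp_index <- a[["intercept"]] + a[["age"]] * cand$age_at_listing[rec] +
      a[["kdpi"]] * don$kdpi[i] + a[["epts"]] * cand$epts[rec]
    tp <- unname(tp_index + errs[i, "xi"]) > 0
    rule <- NA_integer_

    bsize <- config$btd_sizes[sample.int(length(config$btd_sizes), 1,
                                         prob = config$btd_size_probs)]
    rest <- setdiff(avail, rec)
    if (tp && length(rest) < bsize) {
      if (!warned) {
        warning("batch size exceeds waiting-list length for some runs; ",
                "targeting event(s) skipped", call. = FALSE)
        warned <- TRUE
      }
      tp <- FALSE
    }

    other_pool <- which(cand$txp_id != txp & cand$listing_date < odate)
    n_above_other <- sample(0:3, 1)
    n_below <- sample(1:4, 1)
    above_other <- if (n_above_other > 0 && length(other_pool) >= n_above_other)
      sample_idx(other_pool, n_above_other) else integer()
    below_pool <- setdiff(other_pool, above_other)
    below <- sample_idx(below_pool, min(n_below, length(below_pool)))
    n_above_other <- length(above_other)

    if (tp) {
      rule <- sample(1:3, 1, prob = config$rule_mix)
      skipped <- sample_idx(rest, bsize)
      # occasional extra same-program decliners below the recipient keep the
      # response group above the eligibility cutoff for small batches
      extra_pool <- setdiff(rest, skipped)
      n_extra <- min(sample(0:2, 1), length(extra_pool))
      extra <- sample_idx(extra_pool, n_extra)
      above <- c(skipped, above_other)
      ord <- sample(length(above))
      above <- above[ord]
      seq_above <- seq_along(above)
      rec_seq <- length(above) + 1L

      t_b <- t_r + 60 * sample(0:120, 1)
      if (config$jitter_sd > 0) {
        t_batch_i <- floor_minute(t_b + 60 * round(stats::rnorm(bsize, 0, config$jitter_sd)))
      } else {
        t_batch_i <- rep(t_b, bsize)
      }
      if (rule == 1L) {
        batch_code <- "N"; batch_final <- "N"
        t_batch_f <- t_b + 60 * sample(30:600, bsize, TRUE)
        rec_init <- if (stats::runif(1) < 0.8) "Y" else "Z"
        rec_t_f <- t_r + 60 * sample(10:240, 1)
      } else if (rule == 2L) {
        batch_code <- "Z"; batch_final <- "N"
        t_batch_f <- t_b + 60 * sample(30:600, bsize, TRUE)
        if (stats::runif(1) < 0.6) {
          rec_init <- "Y"; rec_t_f <- t_r + 60 * sample(10:240, 1)
        } else {
          rec_init <- "Z"; rec_t_f <- t_r  # provisional finalized at same minute
        }
      } else {
        batch_code <- "Z"; batch_final <- "N"
        rec_init <- "Z"
        rec_t_f <- t_r + 60 * sample(60:600, 1)
        # finals strictly after both the recipient's final and the batch
        # initial, so record timestamps stay internally consistent
        t_batch_f <- pmax(rec_t_f, t_b) + 60 * sample(10:600, bsize, TRUE)
      }
      row_codes_i <- c(rep(batch_code, bsize), rep("N", n_above_other))
      row_t_i <- c(t_batch_i, t_r - 60 * (2 * seq_len(n_above_other) + 1))
      row_codes_f <- c(rep(batch_final, bsize), rep("N", n_above_other))
      row_t_f <- c(t_batch_f, t_r - 60 * (2 * seq_len(n_above_other)))
      ids_above <- c(skipped, above_other)

      k_ex <- seq_len(n_extra)
      run_offers <- tibble::tibble(
        match_run_id = run_id,
        donor_id = don$donor_id[i],
        ptr_id = cand$ptr_id[c(ids_above[ord], rec, below, extra)],
        txp_id = cand$txp_id[c(ids_above[ord], rec, below, extra)],
        sequence_number = c(seq_above, rec_seq,
                            rec_seq + seq_along(c(below, extra))),
        initial_response = c(row_codes_i[ord], rec_init,
                             rep(NA_character_, length(below)),
                             rep("N", n_extra)),
        initial_response_time = c(row_t_i[ord], t_r,
                                  rep(as.POSIXct(NA), length(below)),
                                  t_b + 60 * (600 + 7 * k_ex)),
        final_response = c(row_codes_f[ord], "Y",
                           rep(NA_character_, length(below)),
                           rep("N", n_extra)),
        final_response_time = c(row_t_f[ord], rec_t_f,
                                rep(as.POSIXct(NA), length(below)),
                                t_b + 60 * (601 + 7 * k_ex))
      )
      btd_list[[i]] <- tibble::tibble(
        match_run_id = run_id, ptr_id = cand$ptr_id[skipped],
        batch_time = t_b)
    } else {
      # in-sequence utilization: recipient near the top, distinct decline
      # timestamps above (never forms an identical-time batch)
      n_above <- sample(0:2, 1)
      above_pool <- setdiff(other_pool, c(above_other, below))
      above <- if (n_above > 0 && length(above_pool) >= n_above)
        sample_idx(above_pool, n_above) else integer()
      rec_seq <- length(above) + 1L
      rec_final <- if (stats::runif(1) < config$p_stale_z) "Z" else "Y"
      run_offers <- tibble::tibble(
        match_run_id = run_id,
        donor_id = don$donor_id[i],
        ptr_id = cand$ptr_id[c(above, rec, below)],
        txp_id = cand$txp_id[c(above, rec, below)],
        sequence_number = seq_len(length(above) + 1L + length(below)),
        initial_response = c(rep("N", length(above)), "Y",
                             rep(NA_character_, length(below))),
        initial_response_time = c(t_r - 60 * (3 * rev(seq_along(above))), t_r,
                                  rep(as.POSIXct(NA), length(below))),
        final_response = c(rep("N", length(above)), rec_final,
                           rep(NA_character_, length(below))),
        final_response_time = c(t_r - 60 * (3 * rev(seq_along(above)) - 1), t_r,
                                rep(as.POSIXct(NA), length(below)))
      )
    }

    # bypass-resolved run: OPO skips the top of the list with "B" actions
    if (stats::runif(1) < config$p_bypass) {
      nb <- min(2L, nrow(run_offers) - 1L)
      run_offers$initial_response[seq_len(nb)] <- "B"
      run_offers$final_response[seq_len(nb)] <- "B"
    }
    run_offers$open_offer <- stats::runif(1) < config$p_open_offer
    run_offers$notify_time <- dplyr::if_else(
      stats::runif(nrow(run_offers)) < 0.33,
      run_offers$initial_response_time - 3600, as.POSIXct(NA))

    # refusal codes on declines only
    declined <- !is.na(run_offers$final_response) & run_offers$final_response == "N"
    rc <- rep(NA_character_, nrow(run_offers))
    u <- stats::runif(nrow(run_offers))
    rc[declined & u < config$p_refusal_801] <- "801"
    ft <- declined & u >= config$p_refusal_801 &
      u < config$p_refusal_801 + config$p_freetext
    rc[ft] <- "other: specific stated reason"
    rc[declined & is.na(rc)] <- sample(c("830", "837", "842"),
                                       sum(declined & is.na(rc)), TRUE)
    run_offers$refusal_code <- rc

    offers_list[[i]] <- run_offers
    transplanted_before[rec] <- odate
    tx_list[[i]] <- tibble::tibble(
      match_run_id = run_id,
      donor_id = don$donor_id[i],
      ptr_id = cand$ptr_id[rec],
      txp_id = txp,
      transplant_date = odate + 1,
      true_tp = tp,
      rule_id = rule,
      xi = errs[i, "xi"],
      eps = errs[i, "eps"],
      dual = as.integer(stats::runif(1) < config$p_dual),
      multi_organ = as.integer(stats::runif(1) < config$p_multi_organ)
    )
  }

  offers <- dplyr::bind_rows(offers_list)
  if (nrow(offers) == 0) offers <- empty_offers()
  for (cn in c("initial_response_time", "final_response_time", "notify_time")) {
    attr(offers[[cn]], "tzone") <- "UTC"
  }
  skel <- dplyr::bind_rows(tx_list)
  if (nrow(skel) == 0) {
    return(list(offers = offers, transplants_skeleton = NULL,
                truth = empty_truth(config)))
  }
  btd <- dplyr::bind_rows(btd_list)
  if (nrow(btd) == 0) {
    btd <- tibble::tibble(match_run_id = character(), ptr_id = character(),
                          batch_time = as.POSIXct(character(), tz = "UTC"))
  }
  truth <- structure(
    list(
      true_tp = skel[c("match_run_id", "donor_id", "ptr_id", "true_tp",
                       "rule_id", "xi", "eps")],
      btd_memberships = btd,
      params = config
    ),
    class = "ground_truth"
  )
  list(offers = offers, transplants_skeleton = skel, truth = truth)
}

empty_offers <- function() {
  tibble::tibble(
    match_run_id = character(), donor_id = character(), ptr_id = character(),
    txp_id = character(), sequence_number = integer(),
    initial_response = character(), initial_response_time = as.POSIXct(character()),
    final_response = character(), final_response_time = as.POSIXct(character()),
    notify_time = as.POSIXct(character()), refusal_code = character(),
    open_offer = logical()
  )
}

empty_truth <- function(config) {
  structure(list(
    true_tp = tibble::tibble(match_run_id = character(), donor_id = character(),
                             ptr_id = character(), true_tp = logical(),
                             rule_id = integer(), xi = numeric(), eps = numeric()),
    btd_memberships = tibble::tibble(match_run_id = character(),
                                     ptr_id = character(),
                                     batch_time = as.POSIXct(character())),
    params = config
  ), class = "ground_truth")
}

#' Simulate one-year survival outcomes for the generated transplants
#'
#' Applies the latent outcome equation to every transplanted pair using the
#' disturbance drawn jointly with the treatment disturbance, so the realized
#' treatment indicator is endogenous whenever `rho != 0`. Cold ischemia time
#' is drawn with a longer mean for targeted placements (they sit deeper in
#' the match run).
#'
#' @param sim output of [simulate_match_runs()].
#' @param registry output of [simulate_registry()].
#' @param config a [sim_config()].
#' @return a transplants tibble (one row per transplanted kidney).
#' @export
simulate_outcomes <- function(sim, registry, config) {
  stopifnot(inherits(config, "sim_config"), abs(config$rho) < 1)
  set.seed(derive_seed(config$seed, "outcomes"))
  skel <- sim$transplants_skeleton
  if (is.null(skel) || nrow(skel) == 0) {
    return(tibble::tibble(
      donor_id = character(), ptr_id = character(), txp_id = character(),
      transplant_date = as.Date(character()), cit_hours = numeric(),
      time_to_transplant = numeric(), survival_1yr = integer(),
      dual = integer(), multi_organ = integer()))
  }
  don <- registry$donors
  cand <- registry$candidates
  b <- config$outcome_coeffs
  di <- match(skel$donor_id, don$donor_id)
  ci <- match(skel$ptr_id, cand$ptr_id)
  cit <- pmax(stats::rnorm(nrow(skel),
                           ifelse(skel$true_tp, config$cit_mean_tp,
                                  config$cit_mean_ntp), config$cit_sd), 2)
  ttt <- as.numeric(skel$transplant_date - cand$listing_date[ci]) / 365.25
  ystar <- b[["intercept"]] + b[["tp"]] * skel$true_tp +
    b[["kdpi"]] * don$kdpi[di] + b[["age"]] * cand$age_at_listing[ci] +
    b[["epts"]] * cand$epts[ci] + b[["cit"]] * cit + skel$eps
  tibble::tibble(
    donor_id = skel$donor_id,
    ptr_id = skel$ptr_id,
    txp_id = skel$txp_id,
    transplant_date = skel$transplant_date,
    cit_hours = cit,
    time_to_transplant = ttt,
    survival_1yr = as.integer(ystar > 0),
    dual = skel$dual,
    multi_organ = skel$multi_organ
  )
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Convenience wrapper running [simulate_registry()],
#' [simulate_match_runs()] and [simulate_outcomes()] and assembling a
#' validated [tp_cohort()].
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `tp_cohort`) and `truth` (a `ground_truth`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  reg <- simulate_registry(config)
  sim <- simulate_match_runs(reg, config)
  tx <- simulate_outcomes(sim, reg, config)
  cohort <- tp_cohort(sim$offers, reg$donors, reg$candidates, tx)
  cohort <- log_step(cohort, "simulate", nrow(sim$offers), nrow(sim$offers))
  list(cohort = cohort, truth = sim$truth)
}

#' Simulate transplant-level data from the endogenous-treatment process
#'
#' Draws covariates, the correlated disturbance pair, the realized treatment
#' and the binary outcome directly at the transplant level — the estimation
#' cohort without the match-run mechanics. Used for parameter-recovery
#' studies of the treatment models at large n.
#'
#' @param n number of transplants.
#' @param tp_propensity,outcome_coeffs,rho as in [sim_config()].
#' @param seed integer seed.
#' @return tibble with covariates, `tp` and `survival_1yr`.
#' @export
simulate_treatment_data <- function(n,
                                    tp_propensity = c(intercept = -2.70,
                                                      age = 0.026,
                                                      kdpi = 0.395,
                                                      epts = -0.613),
                                    outcome_coeffs = c(intercept = 2.8, tp = 0,
                                                       kdpi = -0.8, age = -0.01,
                                                       epts = -0.6, cit = -0.005),
                                    rho = 0,
                                    seed = 1L) {
  stopifnot(abs(rho) < 1)
  set.seed(as.integer(seed))
  z_age <- stats::rnorm(n)
  age <- pmin(pmax(52 + 13 * z_age, 18), 85)
  kdpi <- stats::pnorm(stats::qnorm(0.43) * sqrt(2) + 0.8 * stats::rnorm(n) +
                         0.6 * stats::rnorm(n))
  epts <- stats::pnorm(stats::qnorm(0.5) * sqrt(2) + 0.8 * z_age +
                         0.6 * stats::rnorm(n))
  cit <- pmax(stats::rnorm(n, 17, 5), 2)
  errs <- draw_errors(n, rho)
  a <- tp_propensity
  tp <- as.integer(a[["intercept"]] + a[["age"]] * age + a[["kdpi"]] * kdpi +
                     a[["epts"]] * epts + errs[, "xi"] > 0)
  b <- outcome_coeffs
  y <- as.integer(b[["intercept"]] + b[["tp"]] * tp + b[["kdpi"]] * kdpi +
                    b[["age"]] * age + b[["epts"]] * epts + b[["cit"]] * cit +
                    errs[, "eps"] > 0)
  tibble::tibble(age_at_listing = age, kdpi = kdpi, epts = epts,
                 cit_hours = cit, tp = tp, survival_1yr = y)
}
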