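#' Configuration for the cohort preparation chain
#'
#' The preparation chain removes atypical accept/decline instances and
#' out-of-sequence placements with a justifiable cause before labeling.
#' Its seven steps, applied in a fixed order, are individually toggleable so
#' that alternative reconstructions of registry cleaning can be compared.
#'
#' @param enabled_steps ordered subset of the seven step names (default all):
#'   `date_window`, `pediatric`, `dual_kidney`, `multi_organ`, `bypass`,
#'   `open_offer`, `atypical`.
#' @param date_range two dates bounding the study window.
#' @param pediatric_age age cutoff (years) below which donors/recipients are
#'   pediatric and excluded.
#' @param rc1 also apply the refusal-code filter ([filter_refusal_801()])
#'   before labeling (robustness variant).
#' @return a `prep_config` list.
#' @export
prep_config <- function(enabled_steps = c("date_window", "pediatric",
                                          "dual_kidney", "multi_organ",
                                          "bypass", "open_offer", "atypical"),
                        date_range = as.Date(c("2015-01-01", "2018-12-31")),
                        pediatric_age = 18,
                        rc1 = FALSE) {
  all_steps <- c("date_window", "pediatric", "dual_kidney", "multi_organ",
                 "bypass", "open_offer", "atypical")
  unknown <- setdiff(enabled_steps, all_steps)
  if (length(unknown)) {
    stop("config error: unknown preparation step(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(enabled_steps = all_steps[all_steps %in% enabled_steps],
                 date_range = as.Date(date_range),
                 pediatric_age = pediatric_age, rc1 = rc1),
            class = "prep_config")
}

#' Normalize stale provisional-yes responses
#'
#' When a kidney was accepted and transplanted into a candidate but the
#' recorded terminal response remained a provisional yes ("Z"), the final
#' response is reinterpreted as an acceptance ("Y"). All other codes are
#' unchanged; the number of reinterpretations is logged in the provenance.
#'
#' @param cohort a [tp_cohort()].
#' @return the cohort with normalized final responses.
#' @export
normalize_responses <- function(cohort) {
  stopifnot(inherits(cohort, "tp_cohort"))
  of <- cohort$offers
  txkey <- paste(cohort$transplants$donor_id, cohort$transplants$ptr_id)
  stale <- !is.na(of$final_response) & of$final_response == "Z" &
    paste(of$donor_id, of$ptr_id) %in% txkey
  of$final_response[stale] <- "Y"
  cohort$offers <- of
  log_step(cohort, sprintf("normalize_z_to_y (%d changed)", sum(stale)),
           nrow(of), nrow(of))
}

# Drop offers (and transplants) by match-run ids / transplant keys.
drop_runs <- function(cohort, run_ids) {
  of <- cohort$offers
  drop_tx <- of$match_run_id %in% run_ids &
    paste(of$donor_id, of$ptr_id) %in%
      paste(cohort$transplants$donor_id, cohort$transplants$ptr_id)
  txdrop <- paste(of$donor_id[drop_tx], of$ptr_id[drop_tx])
  cohort$offers <- of[!of$match_run_id %in% run_ids, ]
  keep <- !paste(cohort$transplants$donor_id, cohort$transplants$ptr_id) %in% txdrop
  cohort$transplants <- cohort$transplants[keep, ]
  cohort
}

#' Apply the seven-step preparation chain
#'
#' In order: (1) restrict offers to the study date window; (2) drop
#' pediatric donors and recipients; (3) drop dual-kidney transplants;
#' (4) drop multi-organ transplants; (5) drop match runs resolved by a
#' bypass ("B") action; (6) drop open-offer placements; (7) drop atypical or
#' inconsistent records (timestamp order violations, acceptances with no
#' transplant). Each step logs its in/out offer counts in the provenance.
#'
#' @param cohort a normalized [tp_cohort()].
#' @param config a [prep_config()].
#' @return the study cohort with a telescoping provenance log.
#' @export
apply_prep_pipeline <- function(cohort, config = prep_config()) {
  stopifnot(inherits(cohort, "tp_cohort"), inherits(config, "prep_config"))
  for (step in config$enabled_steps) {
    n_in <- nrow(cohort$offers)
    cohort <- switch(
      step,
      date_window = {
        run_dates <- cohort$offers |>
          dplyr::group_by(.data$match_run_id) |>
          dplyr::summarise(d = suppressWarnings(
            min(as.Date(.data$initial_response_time), na.rm = TRUE)))
        out <- run_dates$match_run_id[
          is.finite(as.numeric(run_dates$d)) &
            (run_dates$d < config$date_range[1] | run_dates$d > config$date_range[2])]
        drop_runs(cohort, out)
      },
      pediatric = {
        ped_d <- cohort$donors$donor_id[cohort$donors$age < config$pediatric_age]
        ped_c <- cohort$candidates$ptr_id[
          cohort$candidates$age_at_listing < config$pediatric_age]
        runs_ped_donor <- unique(cohort$offers$match_run_id[
          cohort$offers$donor_id %in% ped_d])
        cohort <- drop_runs(cohort, runs_ped_donor)
        # pediatric recipients: drop their offers and transplants
        cohort$offers <- cohort$offers[!cohort$offers$ptr_id %in% ped_c, ]
        cohort$transplants <- cohort$transplants[
          !cohort$transplants$ptr_id %in% ped_c, ]
        cohort
      },
      dual_kidney = {
        bad <- cohort$transplants[cohort$transplants$dual == 1, ]
        cohort$transplants <- cohort$transplants[cohort$transplants$dual != 1, ]
        cohort$offers <- cohort$offers[
          !paste(cohort$offers$donor_id, cohort$offers$ptr_id) %in%
            paste(bad$donor_id, bad$ptr_id), ]
        cohort
      },
      multi_organ = {
        bad <- cohort$transplants[cohort$transplants$multi_organ == 1, ]
        cohort$transplants <- cohort$transplants[
          cohort$transplants$multi_organ != 1, ]
        cohort$offers <- cohort$offers[
          !paste(cohort$offers$donor_id, cohort$offers$ptr_id) %in%
            paste(bad$donor_id, bad$ptr_id), ]
        cohort
      },
      bypass = {
        runs <- unique(cohort$offers$match_run_id[
          (!is.na(cohort$offers$initial_response) &
             cohort$offers$initial_response == "B") |
            (!is.na(cohort$offers$final_response) &
               cohort$offers$final_response == "B")])
        drop_runs(cohort, runs)
      },
      open_offer = {
        runs <- unique(cohort$offers$match_run_id[cohort$offers$open_offer])
        drop_runs(cohort, runs)
      },
      atypical = {
        of <- cohort$offers
        bad_time <- !is.na(of$initial_response_time) &
          !is.na(of$final_response_time) &
          of$final_response_time < of$initial_response_time
        txkey <- paste(cohort$transplants$donor_id, cohort$transplants$ptr_id)
        accepted_no_tx <- !is.na(of$final_response) & of$final_response == "Y" &
          !paste(of$donor_id, of$ptr_id) %in% txkey
        cohort$offers <- of[!(bad_time | accepted_no_tx), ]
        cohort
      }
    )
    cohort <- log_step(cohort, paste0("prep_", step), n_in, nrow(cohort$offers))
  }
  if (isTRUE(config$rc1)) cohort <- filter_refusal_801(cohort)
  validate_cohort(cohort)
  cohort
}

#' Remove declines with refusal code 801 or a free-text reason
#'
#' Robustness variant of the study cohort: offers declined for code 801
#' ("patient ill, unavailable, refused, or temporarily unsuitable") or with
#' a specific free-text refusal reason are removed before labeling, since
#' such turn downs have a stated justification. Remaining offers re-enter
#' labeling unchanged.
#'
#' @param cohort a [tp_cohort()].
#' @return the filtered cohort.
#' @export
filter_refusal_801 <- function(cohort) {
  stopifnot(inherits(cohort, "tp_cohort"))
  of <- cohort$offers
  rc <- of$refusal_code
  numericish <- grepl("^[0-9]+$", rc)
  drop <- !is.na(rc) & (rc == "801" | !numericish)
  cohort$offers <- of[!drop, ]
  log_step(cohort, "filter_refusal_801", nrow(of), nrow(cohort$offers))
}
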