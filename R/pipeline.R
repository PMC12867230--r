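#' Pipeline run configuration
#'
#' @param stages ordered prefix-closed subset of the pipeline stages
#'   `simulate`, `prep`, `label`, `describe`, `estimate`, `dml`,
#'   `experiments`.
#' @param sim a [sim_config()].
#' @param prep a [prep_config()].
#' @param threshold minimum batch size for labeling.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "prep", "label", "describe"),
                       sim = sim_config(), prep = prep_config(),
                       threshold = 4L, seed = 1L) {
  all_stages <- c("simulate", "prep", "label", "describe", "estimate",
                  "dml", "experiments")
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    stop("config error: unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  prereq <- list(prep = "simulate", label = "prep", describe = "label",
                 estimate = "label", dml = "label", experiments = "label")
  for (s in stages) {
    if (!is.null(prereq[[s]]) && !prereq[[s]] %in% stages) {
      stop("config error: stage '", s, "' requires stage '", prereq[[s]], "'",
           call. = FALSE)
    }
  }
  structure(list(stages = all_stages[all_stages %in% stages], sim = sim,
                 prep = prep, threshold = as.integer(threshold),
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> prep -> label -> describe -> estimate -> dml ->
#' experiments per the configured stage list, deriving each stage's seed
#' from the master seed so a run is replayable end to end. Returns all
#' stage outputs plus a manifest of per-stage record counts.
#'
#' @param config a [run_config()].
#' @return a list with the stage outputs (`cohort`, `truth`, `labels`,
#'   `summary`, `fit_exogenous`, `fit_endogenous`, `dml`, `counterfactual`,
#'   `missed_opportunity`, `placebo`, as requested) and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- list()
  manifest <- list()
  note <- function(stage, n) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(stage = stage, n = n)
  }

  simcfg <- config$sim
  simcfg$seed <- derive_seed(config$seed, "simulate")
  sc <- simulate_cohort(simcfg)
  out$truth <- sc$truth
  cohort <- sc$cohort
  note("simulate", nrow(cohort$offers))

  if ("prep" %in% config$stages) {
    cohort <- normalize_responses(cohort)
    cohort <- apply_prep_pipeline(cohort, config$prep)
    note("prep", nrow(cohort$offers))
  }
  out$cohort <- cohort

  if ("label" %in% config$stages) {
    out$labels <- label_cohort(cohort, threshold = config$threshold)
    note("label", sum(out$labels$labels$label == "TP"))
  }
  if ("describe" %in% config$stages) {
    out$summary <- cohort_summary(out$labels, cohort)
    note("describe", nrow(out$summary$group_sizes))
  }
  if (any(c("estimate", "dml", "experiments") %in% config$stages)) {
    est <- estimation_table(cohort, out$labels)
    out$estimation_table <- est
  }
  if ("estimate" %in% config$stages) {
    out$fit_exogenous <- fit_treatment_probit(
      est, "survival_1yr", "tp",
      step1_covariates = c("age_at_listing", "kdpi", "epts"),
      controls = c("kdpi", "age_at_listing", "epts", "cit_hours"),
      mode = "exogenous")
    out$fit_endogenous <- fit_treatment_probit(
      est, "survival_1yr", "tp",
      step1_covariates = c("age_at_listing", "kdpi", "epts"),
      controls = c("kdpi", "age_at_listing", "epts", "cit_hours"),
      mode = "endogenous")
    note("estimate", est |> nrow())
  }
  if ("dml" %in% config$stages) {
    out$dml <- crossfit_plm(
      est, "survival_1yr", "tp",
      controls = c("kdpi", "age_at_listing", "epts", "cit_hours"),
      config = dml_config(seed = derive_seed(config$seed, "dml")))
    note("dml", out$dml$n_obs)
  }
  if ("experiments" %in% config$stages) {
    out$counterfactual <- counterfactual_tp(est)
    out$missed_opportunity <- missed_opportunity_btd(cohort, out$labels)
    out$placebo <- placebo_test(est, n_replicates = 5L,
                                seed = derive_seed(config$seed, "placebo"))
    note("experiments", out$counterfactual$n_tp)
  }
  out$manifest <- dplyr::bind_rows(manifest)
  out
}

#' Reported cohort-flow shares of the national study
#'
#' The published study's cohort-flow counts (transplants, donors, skipped
#' candidates, missed-opportunity counts) with their printed percentages,
#' shipped as package data, and the share recomputed by the package's
#' reporting arithmetic ([count_share()]) at the printed precision.
#'
#' @return tibble with `quantity`, `count`, `total`, `printed_pct` and the
#'   recomputed `share_pct`.
#' @export
study_flow_table <- function() {
  path <- system.file("extdata", "study_counts.csv", package = "kidneytp")
  df <- tibble::as_tibble(utils::read.csv(path))
  df$share_pct <- mapply(count_share, df$count, df$total, df$printed_digits)
  df
}
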