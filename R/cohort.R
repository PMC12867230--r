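#' Assemble a match-run cohort
#'
#' A cohort bundles the four registry tables of an allocation study: the
#' offer-level match-run records, and the donor, candidate and transplant
#' registries, together with a provenance log of every preparation step
#' applied so far.
#'
#' Offers carry one row per donor-candidate (PTR) match: the 1-based
#' priority `sequence_number` (1 = highest priority), the program's initial
#' and final responses in the code alphabet Y (accept), N (decline),
#' Z (provisional yes), B (bypass), their minute-resolution timestamps, and
#' an optional refusal code (numeric code such as 801, or free text).
#'
#' @param offers tibble of offer rows (see [matchrun_schema()]).
#' @param donors tibble of donor records (KDPI in `[0,1]`, age, clinical covariates).
#' @param candidates tibble of candidate records (EPTS in `[0,1]`, program, DSA).
#' @param transplants tibble of realized transplants with outcomes.
#' @param provenance tibble logging `(step, n_in, n_out)` per preparation step.
#' @param validate run integrity checks (referential integrity, code alphabet,
#'   timestamp ordering, duplicate keys).
#' @return an object of class `tp_cohort`.
#' @export
tp_cohort <- function(offers, donors, candidates, transplants,
                      provenance = NULL, validate = TRUE) {
  provenance <- provenance %||%
    tibble::tibble(step = character(), n_in = integer(), n_out = integer())
  x <- structure(
    list(
      offers = tibble::as_tibble(offers),
      donors = tibble::as_tibble(donors),
      candidates = tibble::as_tibble(candidates),
      transplants = tibble::as_tibble(transplants),
      provenance = tibble::as_tibble(provenance)
    ),
    class = "tp_cohort"
  )
  if (validate) validate_cohort(x)
  x
}

#' @export
print.tp_cohort <- function(x, ...) {
  cat("<tp_cohort>\n")
  cat(sprintf("  offers:      %d\n", nrow(x$offers)))
  cat(sprintf("  donors:      %d\n", nrow(x$donors)))
  cat(sprintf("  candidates:  %d\n", nrow(x$candidates)))
  cat(sprintf("  transplants: %d\n", nrow(x$transplants)))
  if (nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("    %-28s %7d -> %7d\n", x$provenance$step[i],
                  x$provenance$n_in[i], x$provenance$n_out[i]))
    }
  }
  invisible(x)
}

#' Column dictionary for the cohort tables
#'
#' Returns, per table, the mandatory columns and their types. This is the
#' documented on-disk schema of the delimited files read by [read_tables()].
#'
#' @return named list of character vectors (column name -> type).
#' @export
matchrun_schema <- function() {
  list(
    offers = c(
      match_run_id = "character", donor_id = "character",
      ptr_id = "character", txp_id = "character",
      sequence_number = "integer",
      initial_response = "character", initial_response_time = "timestamp",
      final_response = "character", final_response_time = "timestamp",
      notify_time = "timestamp", refusal_code = "character",
      open_offer = "logical"
    ),
    donors = c(
      donor_id = "character", kdpi = "numeric", age = "numeric",
      race = "character", diabetes = "integer", creatinine = "numeric",
      cause_of_death = "character"
    ),
    candidates = c(
      ptr_id = "character", txp_id = "character", dsa_id = "character",
      epts = "numeric", age_at_listing = "numeric", sex = "character",
      race = "character", listing_date = "date"
    ),
    transplants = c(
      donor_id = "character", ptr_id = "character", txp_id = "character",
      transplant_date = "date", cit_hours = "numeric",
      time_to_transplant = "numeric", survival_1yr = "integer",
      dual = "integer", multi_organ = "integer"
    )
  )
}

validate_cohort <- function(x) {
  of <- x$offers
  if (nrow(of)) {
    key <- paste(of$match_run_id, of$ptr_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("integrity error: duplicate (match_run_id, ptr_id) key: ", dup,
           call. = FALSE)
    }
    seqkey <- paste(of$match_run_id, of$sequence_number)
    if (anyDuplicated(seqkey)) {
      stop("integrity error: duplicate sequence_number within match run: ",
           seqkey[duplicated(seqkey)][1], call. = FALSE)
    }
    bad <- !is.na(of$initial_response) & !of$initial_response %in% RESPONSE_CODES
    bad <- bad | (!is.na(of$final_response) & !of$final_response %in% RESPONSE_CODES)
    if (any(bad)) {
      stop("schema error: response codes outside {Y,N,Z,B} in rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(x$donors) && any(x$donors$kdpi < 0 | x$donors$kdpi > 1, na.rm = TRUE)) {
    stop("schema error: kdpi outside [0,1]", call. = FALSE)
  }
  if (nrow(x$candidates) && any(x$candidates$epts < 0 | x$candidates$epts > 1, na.rm = TRUE)) {
    stop("schema error: epts outside [0,1]", call. = FALSE)
  }
  tx <- x$transplants
  if (nrow(tx)) {
    if (!all(tx$donor_id %in% x$donors$donor_id)) {
      miss <- setdiff(tx$donor_id, x$donors$donor_id)
      stop("integrity error: transplant donor_id not in donor registry: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    if (!all(tx$ptr_id %in% x$candidates$ptr_id)) {
      miss <- setdiff(tx$ptr_id, x$candidates$ptr_id)
      stop("integrity error: transplant ptr_id not in candidate registry: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  pv <- x$provenance
  if (nrow(pv) > 1 && any(pv$n_in[-1] != pv$n_out[-nrow(pv)])) {
    stop("integrity error: provenance log counts do not telescope", call. = FALSE)
  }
  invisible(x)
}

#' Read the cohort tables from delimited files
#'
#' Reads `offers.csv`, `donors.csv`, `candidates.csv` and `transplants.csv`
#' from a directory (or explicit paths), parses ISO-8601 minute-resolution
#' timestamps, and validates the result. Empty cells are the missing-value
#' sentinel.
#'
#' @param dir directory containing the four CSV tables, or a named list of
#'   paths with elements `offers`, `donors`, `candidates`, `transplants`.
#' @return a validated [tp_cohort()].
#' @export
read_tables <- function(dir) {
  paths <- if (is.list(dir)) dir else {
    stats::setNames(
      as.list(file.path(dir, paste0(names(matchrun_schema()), ".csv"))),
      names(matchrun_schema())
    )
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  sch <- matchrun_schema()
  tabs <- lapply(names(sch), function(tb) {
    df <- utils::read.csv(paths[[tb]], colClasses = "character",
                          check.names = FALSE, na.strings = "")
    need <- names(sch[[tb]])
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("schema error in ", tb, ": missing mandatory column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- df[need]
    for (cn in need) {
      df[[cn]] <- switch(
        sch[[tb]][[cn]],
        character = df[[cn]],
        integer = as.integer(df[[cn]]),
        numeric = as.numeric(df[[cn]]),
        logical = as.logical(df[[cn]]),
        timestamp = parse_ts(df[[cn]]),
        date = as.Date(df[[cn]])
      )
    }
    tibble::as_tibble(df)
  })
  names(tabs) <- names(sch)
  tp_cohort(tabs$offers, tabs$donors, tabs$candidates, tabs$transplants)
}

#' Write the cohort tables to delimited files
#'
#' Inverse of [read_tables()]: serializes timestamps as ISO-8601 at minute
#' resolution and missing values as empty cells, so that a written cohort
#' reads back equal on every field.
#'
#' @param cohort a [tp_cohort()].
#' @param dir output directory (created if absent).
#' @return the four file paths, invisibly.
#' @export
write_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sch <- matchrun_schema()
  paths <- character()
  for (tb in names(sch)) {
    df <- as.data.frame(cohort[[tb]])
    for (cn in names(sch[[tb]])) {
      df[[cn]] <- switch(
        sch[[tb]][[cn]],
        timestamp = format_ts(df[[cn]]),
        date = ifelse(is.na(df[[cn]]), "", format(df[[cn]], "%Y-%m-%d")),
        df[[cn]]
      )
    }
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths[tb] <- p
  }
  invisible(paths)
}

#' Join offers to registry covariates and outcomes
#'
#' Produces the analysis table with one row per offer: the offer fields plus
#' the donor's covariates, the candidate's covariates, and — where the
#' candidate received that donor's kidney — the transplant and outcome
#' fields (`transplanted` flags these rows). Never fabricates covariates:
#' a dangling foreign key is an error.
#'
#' @param cohort a [tp_cohort()].
#' @return a tibble with one row per offer.
#' @export
link_offers <- function(cohort) {
  stopifnot(inherits(cohort, "tp_cohort"))
  of <- cohort$offers
  dangling_d <- setdiff(of$donor_id, cohort$donors$donor_id)
  dangling_c <- setdiff(of$ptr_id, cohort$candidates$ptr_id)
  if (length(dangling_d) || length(dangling_c)) {
    stop("integrity error: dangling foreign keys in offers: ",
         paste(utils::head(c(dangling_d, dangling_c), 5), collapse = ", "),
         call. = FALSE)
  }
  don <- dplyr::rename(cohort$donors, donor_age = "age", donor_race = "race")
  cand <- dplyr::select(cohort$candidates, -"txp_id")
  tx <- dplyr::mutate(cohort$transplants, transplanted = TRUE)
  out <- of |>
    dplyr::left_join(don, by = "donor_id") |>
    dplyr::left_join(cand, by = "ptr_id") |>
    dplyr::left_join(dplyr::select(tx, -"txp_id"), by = c("donor_id", "ptr_id"))
  out$transplanted[is.na(out$transplanted)] <- FALSE
  stopifnot(nrow(out) == nrow(of))
  out
}

# Append one provenance line, preserving the telescoping invariant.
log_step <- function(cohort, step, n_in, n_out) {
  cohort$provenance <- dplyr::bind_rows(
    cohort$provenance,
    tibble::tibble(step = step, n_in = as.integer(n_in), n_out = as.integer(n_out))
  )
  cohort
}
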