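#' Per-program response groups within match runs
#'
#' Groups offers by (match run, program) keeping only candidates for which
#' the program submitted an initial response (Y, N or Z), ordered by
#' sequence number. A group is eligible for targeted-placement labeling only
#' if it contains at least `min_group` responding candidates.
#'
#' @param offers the offers tibble of a prepared cohort.
#' @param min_group eligibility cutoff on responding candidates (default 5).
#' @return tibble of responding offers with an `eligible` flag, ordered by
#'   `match_run_id`, `txp_id`, `sequence_number`.
#' @export
detect_candidate_groups <- function(offers, min_group = 5L) {
  resp <- offers[!is.na(offers$initial_response) &
                   offers$initial_response %in% c("Y", "N", "Z"), ]
  resp <- resp[order(resp$match_run_id, resp$txp_id, resp$sequence_number), ]
  resp |>
    dplyr::group_by(.data$match_run_id, .data$txp_id) |>
    dplyr::mutate(group_size = dplyr::n(),
                  eligible = dplyr::n() >= min_group) |>
    dplyr::ungroup()
}

# Qualifying batches among higher-ranked responders: identical code ("N" or
# "Z") and identical minute-resolution initial timestamp, size >= threshold,
# and batch time at or after the recipient's initial response time.
candidate_batches <- function(higher, rec_init_time, threshold) {
  if (nrow(higher) == 0) return(list())
  higher <- higher[higher$initial_response %in% c("N", "Z") &
                     !is.na(higher$initial_response_time), ]
  if (nrow(higher) == 0) return(list())
  tmin <- floor_minute(higher$initial_response_time)
  key <- paste(higher$initial_response, as.numeric(tmin))
  out <- list()
  for (k in unique(key)) {
    rows <- higher[key == k, ]
    if (nrow(rows) >= threshold &&
        floor_minute(rows$initial_response_time[1]) >= floor_minute(rec_init_time)) {
      out[[length(out) + 1]] <- rows
    }
  }
  out
}

rule3_final_ok <- function(batch, rec_final_time, transplant_date) {
  ft <- batch$final_response_time
  ok_na <- is.na(ft) # a decline never finalized stays open past the transplant
  ok_later <- !is.na(ft) & !is.na(rec_final_time) & ft > rec_final_time
  ok_day <- if (is.null(transplant_date) || is.na(transplant_date)) {
    FALSE
  } else {
    !is.na(ft) & as.Date(ft, tz = "UTC") >= transplant_date
  }
  ok_na | ok_later | ok_day
}

#' Label one transplant against its program response group
#'
#' Applies the three targeting criteria — (1) an eligible group of at least
#' `min_group` responding candidates at the recipient's program, (2) at
#' least `threshold` higher-ranked candidates sharing one initial code
#' ("N" or "Z") and one initial timestamp, (3) that shared timestamp at or
#' after the recipient's initial response time — then the rule-specific
#' response patterns, in `rule_order` with first match winning:
#'
#' * Rule 1: the batch code is "N" and the recipient's initial response is
#'   "Y" or "Z".
#' * Rule 2: the batch code is "Z" and the recipient's initial response is
#'   "Y", or "Z" with identical initial and final response times.
#' * Rule 3: the batch code is "Z", the recipient's initial response is "Z",
#'   and the batch members' final response times fall after the recipient's
#'   final response time or on/after the transplant day.
#'
#' @param group one (match run, program) response group, ordered by sequence.
#' @param accepted_ptr the `ptr_id` of the transplanted candidate; must be in
#'   the group.
#' @param threshold minimum batch (skipped-candidate) size, default 4.
#' @param transplant_date the transplant date (used by Rule 3).
#' @param min_group eligibility cutoff, default 5.
#' @param rule_order precedence of the three rules.
#' @param strict_rule2 also require Rule 3's final-time condition for
#'   Rule 2's "Z" batches.
#' @return list with `label` ("TP"/"NTP"), `rule_id` (1, 2, 3 or NA),
#'   `batch_code`, `batch_time`, `batch_size`, `skipped_ptr_ids`.
#' @export
label_transplant <- function(group, accepted_ptr, threshold = 4L,
                             transplant_date = NULL, min_group = 5L,
                             rule_order = c(1L, 2L, 3L),
                             strict_rule2 = FALSE) {
  ntp <- list(label = "NTP", rule_id = NA_integer_, batch_code = NA_character_,
              batch_time = as.POSIXct(NA, tz = "UTC"), batch_size = NA_integer_,
              skipped_ptr_ids = character())
  if (!accepted_ptr %in% group$ptr_id) {
    stop("argument error: accepted_ptr ", accepted_ptr,
         " is not in the response group", call. = FALSE)
  }
  if (nrow(group) < min_group) return(ntp)            # criterion (1)
  rec <- group[group$ptr_id == accepted_ptr, ]
  if (is.na(rec$initial_response_time)) return(ntp)
  higher <- group[group$sequence_number < rec$sequence_number, ]
  batches <- candidate_batches(higher, rec$initial_response_time, threshold)
  if (!length(batches)) return(ntp)

  rec_z_same <- !is.na(rec$final_response_time) &&
    floor_minute(rec$initial_response_time) == floor_minute(rec$final_response_time)

  for (r in rule_order) {
    hits <- list()
    for (b in batches) {
      code <- b$initial_response[1]
      if (r == 1L && code == "N" && rec$initial_response %in% c("Y", "Z")) {
        hits[[length(hits) + 1]] <- b
      } else if (r == 2L && code == "Z" &&
                 (rec$initial_response == "Y" ||
                    (rec$initial_response == "Z" && rec_z_same))) {
        if (strict_rule2) {
          keep <- rule3_final_ok(b, rec$final_response_time, transplant_date)
          if (sum(keep) >= threshold) hits[[length(hits) + 1]] <- b[keep, ]
        } else {
          hits[[length(hits) + 1]] <- b
        }
      } else if (r == 3L && code == "Z" && rec$initial_response == "Z") {
        keep <- rule3_final_ok(b, rec$final_response_time, transplant_date)
        if (sum(keep) >= threshold) hits[[length(hits) + 1]] <- b[keep, ]
      }
    }
    if (length(hits)) {
      sizes <- vapply(hits, nrow, 1L)
      times <- vapply(hits, function(b)
        as.numeric(floor_minute(b$initial_response_time[1])), 1)
      best <- hits[[order(-sizes, times)[1]]]
      return(list(
        label = "TP", rule_id = as.integer(r),
        batch_code = best$initial_response[1],
        batch_time = floor_minute(best$initial_response_time[1]),
        batch_size = nrow(best),
        skipped_ptr_ids = best$ptr_id[order(best$sequence_number)]
      ))
    }
  }
  ntp
}

#' Label every transplant in a cohort and collect batch turn downs
#'
#' Runs [label_transplant()] for each transplanted kidney against the
#' recipient's (match run, program) response group. Batch turn-down (BTD)
#' events are recorded only for labeled targeted placements: the skipped
#' higher-ranked candidates of the matched batch form the BTD cohort.
#'
#' @param cohort a prepared [tp_cohort()].
#' @param threshold minimum batch size (4; robustness variants use 3 or 5).
#' @param min_group eligibility cutoff on responding candidates (default 5).
#' @param rule_order,strict_rule2 passed to [label_transplant()].
#' @return object of class `tp_labels`: list with `labels` (one row per
#'   transplant: `label`, `rule_id`, `batch_size`, `threshold`),
#'   `btd_events` (one row per labeled TP) and `btd_members` (one row per
#'   skipped candidate per event).
#' @export
label_cohort <- function(cohort, threshold = 4L, min_group = 5L,
                         rule_order = c(1L, 2L, 3L), strict_rule2 = FALSE) {
  stopifnot(inherits(cohort, "tp_cohort"))
  tx <- cohort$transplants
  groups <- detect_candidate_groups(cohort$offers, min_group)
  gkey <- paste(groups$match_run_id, groups$txp_id)
  gsplit <- split(seq_len(nrow(groups)), gkey)
  of <- cohort$offers
  run_of_tx <- of$match_run_id[match(paste(tx$donor_id, tx$ptr_id),
                                     paste(of$donor_id, of$ptr_id))]

  n <- nrow(tx)
  lab <- character(n); rid <- integer(n); bsz <- integer(n)
  bcode <- character(n); btime <- rep(as.POSIXct(NA, tz = "UTC"), n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    key <- paste(run_of_tx[i], tx$txp_id[i])
    rows <- gsplit[[key]]
    res <- NULL
    if (!is.null(rows) && tx$ptr_id[i] %in% groups$ptr_id[rows]) {
      res <- label_transplant(groups[rows, ], tx$ptr_id[i],
                              threshold = threshold,
                              transplant_date = tx$transplant_date[i],
                              min_group = min_group, rule_order = rule_order,
                              strict_rule2 = strict_rule2)
    }
    if (is.null(res)) {
      lab[i] <- "NTP"; rid[i] <- NA_integer_; bsz[i] <- NA_integer_
      bcode[i] <- NA_character_
    } else {
      lab[i] <- res$label; rid[i] <- res$rule_id; bsz[i] <- res$batch_size
      bcode[i] <- res$batch_code; btime[i] <- res$batch_time
      if (res$label == "TP") {
        events[[i]] <- tibble::tibble(
          match_run_id = run_of_tx[i], donor_id = tx$donor_id[i],
          txp_id = tx$txp_id[i], recipient_ptr_id = tx$ptr_id[i],
          batch_code = res$batch_code, batch_time = res$batch_time,
          batch_size = res$batch_size,
          skipped_ptr_ids = list(res$skipped_ptr_ids))
      }
    }
  }
  btd_events <- dplyr::bind_rows(events)
  if (nrow(btd_events) == 0) {
    btd_events <- tibble::tibble(
      match_run_id = character(), donor_id = character(), txp_id = character(),
      recipient_ptr_id = character(), batch_code = character(),
      batch_time = as.POSIXct(character(), tz = "UTC"),
      batch_size = integer(), skipped_ptr_ids = list())
  }
  btd_members <- if (nrow(btd_events)) {
    tidyr::unnest(
      dplyr::select(btd_events, "match_run_id", "donor_id", "batch_time",
                    ptr_id = "skipped_ptr_ids"),
      cols = "ptr_id")
  } else {
    tibble::tibble(match_run_id = character(), donor_id = character(),
                   batch_time = as.POSIXct(character(), tz = "UTC"),
                   ptr_id = character())
  }
  structure(list(
    labels = tibble::tibble(
      donor_id = tx$donor_id, ptr_id = tx$ptr_id, txp_id = tx$txp_id,
      match_run_id = run_of_tx, label = lab, rule_id = rid,
      batch_code = bcode, batch_time = btime, batch_size = bsz,
      threshold = as.integer(threshold)),
    btd_events = btd_events,
    btd_members = btd_members,
    threshold = as.integer(threshold)
  ), class = "tp_labels")
}

#' @export
print.tp_labels <- function(x, ...) {
  n <- nrow(x$labels)
  ntp <- sum(x$labels$label == "TP")
  cat(sprintf("<tp_labels> %d transplants, %d TP (%.2f%%), threshold %d\n",
              n, ntp, if (n) 100 * ntp / n else 0, x$threshold))
  if (ntp) {
    rc <- table(factor(x$labels$rule_id, levels = 1:3))
    cat(sprintf("  rules 1/2/3: %d / %d / %d\n", rc[1], rc[2], rc[3]))
  }
  invisible(x)
}

#' Classify donors, recipients and candidates by targeting exposure
#'
#' Donors are TP donors if at least one of their kidneys was transplanted as
#' a targeted placement. Recipients are TP or NTP by their own transplant,
#' and BTD recipients if they were part of a batch turn down strictly before
#' their own transplant date. Candidates (transplanted or not) are BTD
#' candidates if they were ever part of a batch turn down.
#'
#' @param labels a [label_cohort()] result.
#' @param cohort the labeled [tp_cohort()].
#' @return list of tibbles `donors` (`donor_class`), `recipients`
#'   (`recipient_class`, `btd_recipient`) and `candidates` (`btd_candidate`).
#' @export
classify_entities <- function(labels, cohort) {
  stopifnot(inherits(labels, "tp_labels"), inherits(cohort, "tp_cohort"))
  lb <- labels$labels
  tp_donors <- unique(lb$donor_id[lb$label == "TP"])
  donors <- tibble::tibble(
    donor_id = unique(lb$donor_id),
    donor_class = ifelse(unique(lb$donor_id) %in% tp_donors, "TP", "NTP"))

  tx <- cohort$transplants
  mem <- labels$btd_members
  btd_before <- vapply(seq_len(nrow(tx)), function(i) {
    j <- mem$ptr_id == tx$ptr_id[i]
    any(j & as.Date(mem$batch_time, tz = "UTC") < tx$transplant_date[i])
  }, logical(1))
  recipients <- tibble::tibble(
    ptr_id = tx$ptr_id,
    recipient_class = lb$label[match(paste(tx$donor_id, tx$ptr_id),
                                     paste(lb$donor_id, lb$ptr_id))],
    btd_recipient = btd_before)

  candidates <- tibble::tibble(
    ptr_id = cohort$candidates$ptr_id,
    btd_candidate = cohort$candidates$ptr_id %in% mem$ptr_id)
  list(donors = donors, recipients = recipients, candidates = candidates)
}
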