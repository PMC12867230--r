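# Shared fixtures and independent oracles.

ts_min <- function(hhmm, day = "2016-05-01") {
  as.POSIXct(paste0(day, " ", hhmm), format = "%Y-%m-%d %H:%M", tz = "UTC")
}

# Build a one-program response group the way detect_candidate_groups would:
# one row per responding candidate, ordered by sequence number.
make_group <- function(seqs, init, init_t, fin = NULL, fin_t = NULL,
                       txp = "T001", run = "MR1") {
  n <- length(seqs)
  tibble::tibble(
    match_run_id = run, txp_id = txp,
    ptr_id = sprintf("P%02d", seqs),
    sequence_number = as.integer(seqs),
    initial_response = init,
    initial_response_time = init_t,
    final_response = fin %||% init,
    final_response_time = if (is.null(fin_t)) init_t else fin_t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force targeting oracle: enumerates every subset of >= threshold
# higher-ranked responders with one shared code ("N"/"Z") and one shared
# minute timestamp at/after the recipient's initial response, then applies
# the rule patterns in order 1, 2, 3. Independent of the implementation.
brute_force_label <- function(group, accepted_ptr, threshold = 4L,
                              transplant_date = NULL, min_group = 5L) {
  flr <- function(x) as.numeric(floor(as.numeric(x) / 60))
  if (nrow(group) < min_group) return(list(label = "NTP", rule_id = NA_integer_))
  rec <- group[group$ptr_id == accepted_ptr, ]
  if (is.na(rec$initial_response_time)) {
    return(list(label = "NTP", rule_id = NA_integer_))
  }
  higher <- group[group$sequence_number < rec$sequence_number &
                    group$initial_response %in% c("N", "Z") &
                    !is.na(group$initial_response_time), ]
  nh <- nrow(higher)
  rec_z_same <- !is.na(rec$final_response_time) &&
    flr(rec$initial_response_time) == flr(rec$final_response_time)
  rule3_ok <- function(rows) {
    ft <- rows$final_response_time
    ok_day <- if (is.null(transplant_date) || is.na(transplant_date)) {
      FALSE
    } else {
      !is.na(ft) & as.Date(ft, tz = "UTC") >= transplant_date
    }
    is.na(ft) |
      (!is.na(rec$final_response_time) & !is.na(ft) & ft > rec$final_response_time) |
      ok_day
  }
  subset_ok <- function(rows) {
    length(unique(rows$initial_response)) == 1 &&
      rows$initial_response[1] %in% c("N", "Z") &&
      length(unique(flr(rows$initial_response_time))) == 1 &&
      flr(rows$initial_response_time[1]) >= flr(rec$initial_response_time)
  }
  for (r in 1:3) {
    if (nh >= threshold) {
      for (k in threshold:nh) {
        for (comb in utils::combn(nh, k, simplify = FALSE)) {
          rows <- higher[comb, ]
          if (!subset_ok(rows)) next
          code <- rows$initial_response[1]
          hit <- switch(
            r,
            code == "N" && rec$initial_response %in% c("Y", "Z"),
            code == "Z" && (rec$initial_response == "Y" ||
                              (rec$initial_response == "Z" && rec_z_same)),
            code == "Z" && rec$initial_response == "Z" && all(rule3_ok(rows)))
          if (isTRUE(hit)) return(list(label = "TP", rule_id = r))
        }
      }
    }
  }
  list(label = "NTP", rule_id = NA_integer_)
}

# Random response group for oracle-agreement testing: heavy timestamp ties
# and batch-like code runs so targeting patterns occur often.
random_group <- function(n = NULL) {
  n <- n %||% sample(5:10, 1)
  mins <- sample(c("09:50", "10:00", "10:00", "10:00", "10:00", "10:10"), n, TRUE)
  init <- sample(c("N", "N", "N", "Z", "Z", "Z", "Y"), n, TRUE)
  fin_delta <- sample(c(0, 0, 15, 120), n, TRUE)
  it <- ts_min(mins)
  g <- make_group(seq_len(n), init, it,
                  fin = ifelse(init == "Y", "Y", sample(c("N", "Z"), n, TRUE)),
                  fin_t = it + 60 * fin_delta)
  # recipient near the bottom of the list, forced responder
  rec_i <- sample(max(2, n - 2):n, 1)
  g$initial_response[rec_i] <- sample(c("Y", "Z"), 1)
  g$final_response[rec_i] <- "Y"
  if (g$initial_response[rec_i] == "Z" && runif(1) < 0.5) {
    g$final_response_time[rec_i] <- g$initial_response_time[rec_i]
  }
  list(group = g, accepted = g$ptr_id[rec_i],
       transplant_date = as.Date("2016-05-01") + sample(0:2, 1))
}

# Small clean simulator config for fast, injection-free cohorts; any
# injection rate can be switched back on through ...
clean_sim <- function(n_donors = 400, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_donors = n_donors, n_candidates = n_donors * 6,
         n_txps = 12, n_dsas = 4,
         p_bypass = 0, p_pediatric_donor = 0, p_pediatric_candidate = 0,
         p_dual = 0, p_multi_organ = 0, p_open_offer = 0, p_stale_z = 0,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Stronger treatment-propensity scale used for parameter-recovery studies:
# enough index variation to identify (beta1, rho) without an exclusion
# restriction.
RECOVERY_PROPENSITY <- c(intercept = -6.5, age = 0.10, kdpi = 1.2, epts = -1.5)

recovery_coeffs <- function(beta1) {
  c(intercept = 2.8, tp = beta1, kdpi = -0.8, age = -0.01, epts = -0.6,
    cit = -0.005)
}

SURV_COVS <- c("kdpi", "age_at_listing", "epts", "cit_hours")
STEP1_COVS <- c("age_at_listing", "kdpi", "epts")

# Linear / nonlinear partially-linear DGP with confounded treatment.
make_plm_data <- function(n, theta, seed, nonlinear = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  g <- if (nonlinear) {
    1.5 * sin(X[, 1]) + X[, 2]^2 - 0.5 * abs(X[, 3])
  } else {
    X %*% c(1, -0.5, 0.25, 0, 0.8)
  }
  m <- if (nonlinear) {
    0.8 * tanh(X[, 1]) + 0.4 * X[, 2]
  } else {
    X %*% c(0.5, 0.5, 0, -0.4, 0)
  }
  p <- as.numeric(m) + rnorm(n)
  y <- theta * p + as.numeric(g) + rnorm(n)
  d <- as.data.frame(X)
  d$p <- p
  d$y <- y
  d
}
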