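# Internal helpers shared across modules.

# Response code alphabet for match-run offers. "B" marks an OPO bypass.
RESPONSE_CODES <- c("Y", "N", "Z", "B")

# Days per month used whenever a day count is reported in months.
DAYS_PER_MONTH <- 30.44

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' seed so that a full pipeline run is replayable stage by stage. Kept below
#' 2^31 so it is always a valid R integer.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483629)
}

# Floor a POSIXct to minute resolution; all "same time" comparisons in the
# labeling rules are exact equality at the minute.
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# Parse/format ISO-8601 minute-resolution timestamps (UTC).
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  out
}

format_ts <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M", tz = "UTC"))
}

# Truncated normal draw via inverse CDF (vectorized, deterministic under seed).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
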