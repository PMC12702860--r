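# Non-uniform cycle schedule: daily cycles while the cohort is mostly in
# hospital, half-monthly cycles for the home follow-up years.

#' Build the model's cycle grid
#'
#' Daily cycles for the first 180 days of model time, then 15-day cycles up
#' to the horizon (the last cycle is truncated so the grid tiles
#' `[0, horizon_days]` exactly). Each cycle carries the home-year cluster
#' (1-5) that its start day falls in; the cluster selects the year-specific
#' home infection, rehospitalisation and mortality inputs.
#'
#' @param horizon_days Positive integer horizon (payer default 1825 days).
#' @return A `data.frame(cycle, start_day, length_days, phase, year_cluster)`.
#' @export
#' @examples
#' g <- build_time_grid(1825)
#' nrow(g)              # 180 daily + 110 half-monthly cycles
#' sum(g$length_days)   # 1825
build_time_grid <- function(horizon_days) {
  if (!is.numeric(horizon_days) || horizon_days < 1) {
    stop("horizon_days must be >= 1", call. = FALSE)
  }
  horizon_days <- as.integer(round(horizon_days))
  n_daily <- min(horizon_days, 180L)
  starts <- 0:(n_daily - 1)
  lengths <- rep(1L, n_daily)
  if (horizon_days > 180L) {
    n_half <- ceiling((horizon_days - 180L) / 15)
    hs <- 180L + 15L * (seq_len(n_half) - 1L)
    hl <- pmin(15L, horizon_days - hs)
    starts <- c(starts, hs)
    lengths <- c(lengths, hl)
  }
  data.frame(
    cycle = seq_along(starts),
    start_day = starts,
    length_days = lengths,
    phase = ifelse(lengths == 1L & starts < 180L, "daily", "half_monthly"),
    year_cluster = pmin(floor(starts / 365) + 1L, 5L)
  )
}

#' Rescale an event probability to a different cycle length
#'
#' Constant-hazard conversion `1 - (1 - p)^(cycle_days / source_period_days)`.
#' Monotone in `p` and in the cycle length; compounding two half-cycles
#' recovers the full-period probability.
#'
#' @param p Probability over `source_period_days` (in `[0, 1)`; `p = 1` is
#'   only admissible when the target cycle is at least as long as the source
#'   period).
#' @param source_period_days Period the probability refers to.
#' @param cycle_days Target cycle length.
#' @return Per-cycle probability.
#' @export
#' @examples
#' to_cycle_prob(0.5, 30, 15)  # 1 - sqrt(0.5)
to_cycle_prob <- function(p, source_period_days, cycle_days) {
  if (any(source_period_days <= 0) || any(cycle_days <= 0)) {
    stop("periods must be positive", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(p == 1 & cycle_days < source_period_days)) {
    stop("p = 1 cannot be rescaled to a shorter cycle (hazard undefined)",
         call. = FALSE)
  }
  1 - (1 - p)^(cycle_days / source_period_days)
}

# Event rate (per period_days) -> per-cycle probability, exponential hazard.
rate_to_cycle_prob <- function(rate, period_days, cycle_days) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  1 - exp(-rate * cycle_days / period_days)
}
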