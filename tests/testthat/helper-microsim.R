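# Event-driven microsimulation oracle: evolves integer head-counts through
# the same per-cycle transition matrices as the cohort engine, drawing every
# transition at the individual level with multinomial sampling. Hospital
# person-time within a cycle is sampled at daily resolution (leavers get a
# truncated-geometric day of exit), so NICU-day accounting matches the
# engine's exposure semantics in expectation while every tally carries
# genuine Monte Carlo noise.

microsim_run <- function(ps, arm, n_ind, horizon_days = 1825, seed = 1) {
  set.seed(seed)
  grid <- build_time_grid(horizon_days)
  inp <- nnsbia:::model_inputs(ps, arm)
  split <- stratify(ps, arm)
  branch <- as.vector(stats::rmultinom(1, n_ind, split$masses / split$n))
  lens <- sort(unique(grid$length_days))
  Ms <- lapply(1:2, function(mk) {
    ms <- lapply(lens, function(L) {
      nnsbia:::transition_matrix_from_inputs(inp, mk, L)
    })
    names(ms) <- as.character(lens)
    ms
  })
  S <- 19L
  home_block <- function(y) 3L + (y - 1L) * 3L + 1:3

  # integer day-starts spent in a state during an L-day cycle by `n_leave`
  # individuals who exit it that cycle (per-cycle exit probability P)
  leaver_days <- function(n_leave, P, L) {
    if (n_leave == 0L || L == 1L) return(n_leave)
    pd <- 1 - (1 - P)^(1 / L)
    q <- 1 - pd
    u <- stats::runif(n_leave)
    sum(ceiling(log(1 - u * (1 - q^L)) / log(q)))
  }

  cnt <- list(integer(S), integer(S))
  cnt[[1]][2] <- branch[1]   # NNS at birth: discharge-eligible from day 0
  cnt[[1]][1] <- branch[2]
  cnt[[2]][1] <- branch[3]
  tal <- c(nicu_days = 0, infections_hospital = 0, ngt_discharges = 0,
           home_infections = 0, rehospitalizations = 0, deaths = 0)

  for (k in seq_len(nrow(grid))) {
    L <- grid$length_days[k]
    y <- grid$year_cluster[k]
    hb <- home_block(y)
    for (mk in 1:2) {
      x <- cnt[[mk]]
      if (grid$start_day[k] == inp$t0) {
        x[2] <- x[2] + x[1]
        x[1] <- 0L
      }
      for (y2 in setdiff(1:5, y)) {
        b2 <- home_block(y2)
        if (any(x[b2] > 0L)) {
          x[hb] <- x[hb] + x[b2]
          x[b2] <- 0L
        }
      }
      M <- Ms[[mk]][[as.character(L)]]
      new <- integer(S)
      hosp_days <- 0
      for (s in which(x > 0L)) {
        if (s == S) {
          new[S] <- new[S] + x[S]
          next
        }
        draw <- as.vector(stats::rmultinom(1, x[s], M[s, ]))
        new <- new + draw
        tal["deaths"] <- tal["deaths"] + draw[S]
        if (s %in% 1:3) {
          P <- 1 - M[s, s]
          days <- draw[s] * L + leaver_days(x[s] - draw[s], P, L)
          hosp_days <- hosp_days + days
          if (s %in% 1:2) tal["nicu_days"] <- tal["nicu_days"] + days
        }
        if (s == hb[1]) {
          tal["home_infections"] <- tal["home_infections"] + draw[hb[2]]
          tal["rehospitalizations"] <- tal["rehospitalizations"] + draw[hb[3]]
        }
        if (mk == 2L && s %in% c(2L, 3L)) {
          tal["ngt_discharges"] <- tal["ngt_discharges"] + draw[4L]
        }
      }
      if (hosp_days > 0) {
        tal["infections_hospital"] <- tal["infections_hospital"] +
          stats::rbinom(1, hosp_days, inp$i_hosp_daily)
      }
      cnt[[mk]] <- new
    }
  }
  tal
}
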