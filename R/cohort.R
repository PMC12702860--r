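# Cohort engine: decision-tree pre-stratification by predicted achievement
# of full oral feeding (FOF), then two structurally identical Markov models
# (Markov 1: FOF achieved in NICU; Markov 2: discharged with a nasogastric
# tube) evolved on the mixed daily/half-monthly grid.

# State space. Home states are replicated in 5 yearly clusters so the home
# follow-up inputs can vary by year since birth; Dead is absorbing.
.N_STATES <- 19L
.S_PRE <- 1L; .S_TRAIN <- 2L; .S_WARD <- 3L; .S_DEAD <- 19L
.S_HOME <- function(y) 3L + (y - 1L) * 3L + 1L
.S_HOMEINF <- function(y) 3L + (y - 1L) * 3L + 2L
.S_REHOSP <- function(y) 3L + (y - 1L) * 3L + 3L

#' State labels of the Markov models
#' @return Character vector of the 19 state names.
#' @export
state_names <- function() {
  c("nicu_pre_training", "nicu_training_followup", "lower_acuity_ward",
    as.vector(t(outer(paste0("year", 1:5),
                      c("home_healthy", "home_infection_managed",
                        "rehospitalized"),
                      function(y, s) paste(s, y, sep = "_")))),
    "dead")
}

#' Modulate the non-FOF discharge probability by the TTD factor
#'
#' The sub-cohort that does not achieve full oral feeding in the NICU is
#' assumed to discharge more slowly; its per-cycle discharge probability is
#' the FOF group's probability scaled linearly by the time-to-discharge
#' (TTD) factor, capped at 1. `ttd = 1` recovers the FOF probability
#' exactly; `ttd > 1` shortens and `ttd < 1` lengthens the stay. Base-case
#' value 0.8.
#'
#' @param p_discharge_fof Per-cycle discharge probability of the FOF group.
#' @param ttd Positive TTD factor.
#' @return Scaled probability.
#' @export
apply_ttd <- function(p_discharge_fof, ttd) {
  if (any(ttd <= 0)) stop("ttd must be > 0", call. = FALSE)
  if (any(p_discharge_fof < 0 | p_discharge_fof > 1)) {
    stop("p_discharge_fof must be in [0, 1]", call. = FALSE)
  }
  pmin(ttd * p_discharge_fof, 1)
}

#' Gestational-age-weighted rehospitalisation rate
#'
#' The home rehospitalisation literature stratifies by gestational age at
#' birth (24-27 vs 28-31 weeks); the modelled 25-30-week cohort uses the
#' mixture of the two rates weighted by its younger-group proportion.
#'
#' @param rate_gab_24_27 Annual rate, younger stratum.
#' @param rate_gab_28_31 Annual rate, older stratum.
#' @param prop_younger Proportion of the cohort in the younger stratum.
#' @return Weighted annual rate.
#' @export
weighted_rehosp_rate <- function(rate_gab_24_27, rate_gab_28_31,
                                 prop_younger) {
  if (any(rate_gab_24_27 < 0) || any(rate_gab_28_31 < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (any(prop_younger < 0 | prop_younger > 1)) {
    stop("prop_younger must be in [0, 1]", call. = FALSE)
  }
  prop_younger * rate_gab_24_27 + (1 - prop_younger) * rate_gab_28_31
}

#' Decision-tree stratification of the cohort
#'
#' Splits the entering cohort of an arm into three branches: infants with
#' non-nutritive sucking already developed at birth (entering Markov 1
#' directly in the achieved-FOF state), infants whose NNS training is
#' predicted to succeed (Markov 1, pre-training state) and infants whose
#' training is predicted to fail (Markov 2, pre-training state).
#'
#' @param ps A `bia_parameters` object.
#' @param arm `"pfos"` or `"soc"`.
#' @return A `bia_split`: list with the three branch masses (patients).
#' @export
stratify <- function(ps, arm = c("pfos", "soc")) {
  arm <- match.arg(tolower(arm), c("pfos", "soc"))
  n <- n_patients(ps)
  a0 <- param_value(ps, "prop_nns_at_birth")
  a2 <- param_value(ps, paste0("prop_fof_fail_", arm))
  if (a0 + a2 > 1 + 1e-12) {
    stop("stratification fractions exceed 1 for arm ", arm, call. = FALSE)
  }
  a1 <- 1 - a0 - a2
  masses <- c(nns_at_birth = n * a0, training_success = n * a1,
              training_fail = n * a2)
  if (abs(sum(masses) - n) > 1e-9) {
    stop("branch masses do not sum to the cohort size", call. = FALSE)
  }
  structure(list(arm = arm, n = n, masses = masses), class = "bia_split")
}

# All engine-level scalars for one arm, derived once per run.
model_inputs <- function(ps, arm) {
  arm <- match.arg(tolower(arm), c("pfos", "soc"))
  v <- function(nm) param_value(ps, nm)
  t_fof <- v("time_to_fof_soc")
  if (arm == "pfos") t_fof <- t_fof * v("time_to_fof_ratio_pfos")
  p1 <- 1 / t_fof
  p_inf_home <- v("p_infection_home_annual")
  odds2 <- p_inf_home / (1 - p_inf_home) * v("or_infection_ngt_home")
  r_base <- weighted_rehosp_rate(v("rehosp_rate_gab_24_27"),
                                 v("rehosp_rate_gab_28_31"),
                                 v("prop_gab_25_28"))
  list(
    arm = arm,
    t0 = as.integer(round(v("training_start_day"))),
    p_discharge = c(p1, apply_ttd(p1, v("ttd"))),  # markov 1, markov 2
    w_ward = v("prop_discharge_to_ward"),
    p_ward_leave_daily = 1 / v("ward_los_mean_days"),
    p_rehosp_leave_daily = 1 / v("rehosp_los_mean_days"),
    m_hosp_daily = v("mort_hospital_daily"),
    m_home_annual = c(v("mort_home_annual_y1"),
                      rep(v("mort_home_annual_later"), 4)),
    i_hosp_daily = v("p_infection_hospital_daily"),
    i_home_annual = c(p_inf_home, odds2 / (1 + odds2)),  # markov 1, markov 2
    rehosp_annual = r_base * c(1, v("rehosp_year_mult_y2"),
                               v("rehosp_year_mult_y3"),
                               v("rehosp_year_mult_y4"),
                               v("rehosp_year_mult_y5"))
  )
}

transition_matrix_from_inputs <- function(inp, markov, cycle_days) {
  L <- cycle_days
  M <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(state_names(), state_names()))
  mh <- to_cycle_prob(inp$m_hosp_daily, 1, L)
  d <- to_cycle_prob(inp$p_discharge[markov], 1, L)
  wl <- to_cycle_prob(inp$p_ward_leave_daily, 1, L)
  rl <- to_cycle_prob(inp$p_rehosp_leave_daily, 1, L)
  w <- inp$w_ward

  # hospital rows: death first, then discharge, residual stays
  M[.S_PRE, .S_DEAD] <- mh
  M[.S_PRE, .S_PRE] <- 1 - mh
  M[.S_TRAIN, .S_DEAD] <- mh
  M[.S_TRAIN, .S_WARD] <- (1 - mh) * d * w
  M[.S_TRAIN, .S_HOME(1)] <- (1 - mh) * d * (1 - w)
  M[.S_TRAIN, .S_TRAIN] <- (1 - mh) * (1 - d)
  M[.S_WARD, .S_DEAD] <- mh
  M[.S_WARD, .S_HOME(1)] <- (1 - mh) * wl
  M[.S_WARD, .S_WARD] <- (1 - mh) * (1 - wl)

  for (y in 1:5) {
    mo <- to_cycle_prob(inp$m_home_annual[y], 365, L)
    ry <- rate_to_cycle_prob(inp$rehosp_annual[y], 365, L)
    iy <- to_cycle_prob(inp$i_home_annual[markov], 365, L)
    h <- .S_HOME(y); hi <- .S_HOMEINF(y); rh <- .S_REHOSP(y)
    M[h, .S_DEAD] <- mo
    M[h, rh] <- (1 - mo) * ry
    M[h, hi] <- (1 - mo) * (1 - ry) * iy
    M[h, h] <- (1 - mo) * (1 - ry) * (1 - iy)
    # home-managed infection is a transient one-cycle state
    M[hi, .S_DEAD] <- mo
    M[hi, h] <- 1 - mo
    # rehospitalised infants face hospital mortality, then return home
    M[rh, .S_DEAD] <- mh
    M[rh, h] <- (1 - mh) * rl
    M[rh, rh] <- (1 - mh) * (1 - rl)
  }
  M[.S_DEAD, .S_DEAD] <- 1

  bad <- abs(rowSums(M) - 1) > 1e-9
  if (any(bad)) {
    stop("transition matrix rows do not sum to 1: ",
         paste(state_names()[bad], collapse = ", "), call. = FALSE)
  }
  M
}

#' Build a per-cycle transition matrix
#'
#' Row-stochastic matrix over the 19-state space for one arm, Markov model
#' and cycle length. All per-period inputs are rescaled to the cycle length
#' by constant-hazard conversion ([to_cycle_prob()]); the Markov 2 discharge
#' probability passes through [apply_ttd()]; within a cycle death takes
#' precedence, then discharge, then home events, with the residual mass
#' remaining in state.
#'
#' @param ps A `bia_parameters` object.
#' @param arm `"pfos"` or `"soc"`.
#' @param markov 1 (FOF achieved) or 2 (discharged with NGT).
#' @param cycle_days Cycle length in days (1 or 15 on the default grid).
#' @return A 19 x 19 row-stochastic matrix.
#' @export
build_transition_matrix <- function(ps, arm, markov, cycle_days) {
  stopifnot(markov %in% c(1, 2))
  transition_matrix_from_inputs(model_inputs(ps, arm), markov, cycle_days)
}

# Expected patient-days in a state during a cycle of L days, for occupancy
# `occ` at cycle start and total per-cycle exit probability `P`. Exposure is
# accounted at daily resolution under a constant within-cycle hazard, so a
# geometric stay of mean 1/p accrues exactly 1/p days on any cycle grid.
cycle_exposure <- function(occ, P, L) {
  if (P < 1e-12) return(occ * L)
  occ * P / (1 - (1 - P)^(1 / L))
}

#' Evolve the cohort through the decision tree and both Markov models
#'
#' Iterates state occupancy over the cycle grid for one arm, tracking
#' hospital patient-day exposure (NICU pre-training, NICU training and
#' follow-up, lower-acuity ward), in-hospital tube infections (exposure-days
#' times the daily infection probability), discharges with nasogastric tube
#' (Markov 2 hospital-to-home flow), home-managed infections,
#' rehospitalisation entries and deaths. The pre-training sub-cohort moves
#' into the training state at the training start day; home occupancy is
#' carried into the current year cluster as the grid crosses 365-day
#' boundaries. Mass is checked for conservation at every cycle.
#'
#' @param ps A `bia_parameters` object.
#' @param arm `"pfos"` or `"soc"`.
#' @param horizon_days Model horizon (default 1825 = 5 years).
#' @return A `bia_trace`: occupancy matrices per Markov model, a per-cycle
#'   ledger of exposures and event flows, the entering split, and the
#'   parameter set that produced it.
#' @export
run_cohort <- function(ps, arm = c("pfos", "soc"), horizon_days = 1825) {
  arm <- match.arg(tolower(arm), c("pfos", "soc"))
  grid <- build_time_grid(horizon_days)
  inp <- model_inputs(ps, arm)
  split <- stratify(ps, arm)
  if (inp$t0 < 0 || inp$t0 >= 180) {
    stop("training_start_day must lie in the daily phase [0, 180)",
         call. = FALSE)
  }

  n_cyc <- nrow(grid)
  lens <- sort(unique(grid$length_days))
  mats <- lapply(1:2, function(mk) {
    ms <- lapply(lens, function(L) transition_matrix_from_inputs(inp, mk, L))
    names(ms) <- as.character(lens)
    ms
  })

  occ0 <- list(
    # Markov 1: NNS-at-birth infants start in the achieved-FOF (training &
    # follow-up) state awaiting discharge; trainees start pre-training.
    {
      o <- numeric(.N_STATES)
      o[.S_TRAIN] <- split$masses[["nns_at_birth"]]
      o[.S_PRE] <- split$masses[["training_success"]]
      o
    },
    {
      o <- numeric(.N_STATES)
      o[.S_PRE] <- split$masses[["training_fail"]]
      o
    }
  )

  home_idx <- lapply(1:5, function(y) c(.S_HOME(y), .S_HOMEINF(y),
                                        .S_REHOSP(y)))
  occupancy <- list()
  ledger <- vector("list", 2)

  for (mk in 1:2) {
    occ <- occ0[[mk]]
    mass0 <- sum(occ)
    occ_mat <- matrix(0, n_cyc, .N_STATES,
                      dimnames = list(NULL, state_names()))
    led <- matrix(0, n_cyc, 8)
    colnames(led) <- c("nicu_pre_days", "nicu_train_days", "ward_days",
                       "infections_hospital", "home_infections",
                       "rehospitalizations", "ngt_discharges", "deaths")
    for (k in seq_len(n_cyc)) {
      L <- grid$length_days[k]
      y <- grid$year_cluster[k]
      if (grid$start_day[k] == inp$t0 && occ[.S_PRE] > 0) {
        occ[.S_TRAIN] <- occ[.S_TRAIN] + occ[.S_PRE]
        occ[.S_PRE] <- 0
      }
      # home mass always lives in the cluster of the current model year
      for (y2 in seq_len(5)[-y]) {
        idx2 <- home_idx[[y2]]; idx <- home_idx[[y]]
        if (any(occ[idx2] > 0)) {
          occ[idx] <- occ[idx] + occ[idx2]
          occ[idx2] <- 0
        }
      }
      M <- mats[[mk]][[as.character(L)]]

      e_pre <- cycle_exposure(occ[.S_PRE], 1 - M[.S_PRE, .S_PRE], L)
      e_train <- cycle_exposure(occ[.S_TRAIN], 1 - M[.S_TRAIN, .S_TRAIN], L)
      e_ward <- cycle_exposure(occ[.S_WARD], 1 - M[.S_WARD, .S_WARD], L)

      h <- .S_HOME(y); hi <- .S_HOMEINF(y); rh <- .S_REHOSP(y)
      flow_inf <- occ[h] * M[h, hi]
      flow_rehosp <- occ[h] * M[h, rh]
      flow_death <- sum(occ[-.S_DEAD] * M[-.S_DEAD, .S_DEAD])
      flow_ngt <- if (mk == 2) {
        occ[.S_TRAIN] * M[.S_TRAIN, .S_HOME(1)] +
          occ[.S_WARD] * M[.S_WARD, .S_HOME(1)]
      } else 0

      led[k, ] <- c(e_pre, e_train, e_ward,
                    (e_pre + e_train + e_ward) * inp$i_hosp_daily,
                    flow_inf, flow_rehosp, flow_ngt, flow_death)

      occ <- as.vector(occ %*% M)
      if (abs(sum(occ) - mass0) > 1e-9) {
        stop("mass conservation violated at cycle ", k, " (markov ", mk, ")",
             call. = FALSE)
      }
      occ_mat[k, ] <- occ
    }
    occupancy[[mk]] <- occ_mat
    df <- as.data.frame(led)
    df <- cbind(data.frame(cycle = grid$cycle, markov = mk), df)
    ledger[[mk]] <- df
  }

  structure(
    list(arm = arm, horizon_days = horizon_days, grid = grid,
         split = split, entering_mass = split$n,
         occupancy = stats::setNames(occupancy, c("markov1", "markov2")),
         ledger = do.call(rbind, ledger), ps = ps),
    class = "bia_trace"
  )
}

#' @export
print.bia_trace <- function(x, ...) {
  out <- extract_outcomes(x)
  cat("<bia_trace> arm ", x$arm, ", horizon ", x$horizon_days, " days, ",
      nrow(x$grid), " cycles\n", sep = "")
  cat(sprintf("  NICU days %.1f | NGT discharges %.2f | rehosp %.2f | deaths %.2f\n",
              out$nicu_days, out$ngt_discharges, out$rehospitalizations,
              out$deaths))
  invisible(x)
}

#' Summarise clinical and resource outcomes of a trace
#'
#' Totals the per-cycle ledger into the headline clinical quantities: NICU
#' patient-days, in-hospital tube infections, discharges with nasogastric
#' tube, home-managed infections, rehospitalisations, deaths and the implied
#' mean NICU length of stay per entering patient. When a comparator trace is
#' supplied, per-category differences (`self - reference`) are attached.
#'
#' @param trace A `bia_trace`.
#' @param reference Optional comparator `bia_trace` (e.g. the SoC arm).
#' @return A `bia_outcomes` list.
#' @export
extract_outcomes <- function(trace, reference = NULL) {
  led <- trace$ledger
  tot <- function(col) sum(led[[col]])
  out <- list(
    arm = trace$arm,
    nicu_days = tot("nicu_pre_days") + tot("nicu_train_days"),
    ward_days = tot("ward_days"),
    infections_hospital = tot("infections_hospital"),
    ngt_discharges = tot("ngt_discharges"),
    home_infections = tot("home_infections"),
    rehospitalizations = tot("rehospitalizations"),
    deaths = tot("deaths")
  )
  out$mean_nicu_los <- out$nicu_days / trace$entering_mass
  if (!is.null(reference)) {
    ref <- extract_outcomes(reference)
    keys <- c("nicu_days", "ward_days", "infections_hospital",
              "ngt_discharges", "home_infections", "rehospitalizations",
              "deaths")
    out$difference <- stats::setNames(
      vapply(keys, function(k) out[[k]] - ref[[k]], numeric(1)), keys)
  }
  structure(out, class = "bia_outcomes")
}
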