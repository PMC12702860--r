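# Perspective-specific costing: attach unit charges/costs to a cohort
# trace, aggregate into care-setting categories, and derive covered lives
# and per-member-per-month figures for the payer view.

#' Define a costing perspective
#'
#' The insurance-payer perspective prices the full five-year horizon on
#' billed hospital charges per day plus per-event costs for home infections,
#' NGT discharges and rehospitalisations. The hospital perspective prices
#' only the first model year, converts charges to incurred costs with the
#' cost-to-charge ratio, excludes all home-care categories, and adds
#' staff time for NNS training, reported separately for the FOF and non-FOF
#' groups.
#'
#' @param name `"payer"` or `"hospital"`.
#' @return A `bia_perspective` list (`name`, `horizon_days`, `basis`).
#' @export
perspective <- function(name = c("payer", "hospital")) {
  name <- match.arg(tolower(name), c("payer", "hospital"))
  structure(
    list(name = name,
         horizon_days = if (name == "payer") 1825 else 365,
         basis = if (name == "payer") "charges" else "costs"),
    class = "bia_perspective"
  )
}

#' Staff time cost of NNS training
#'
#' Hands-on nursing time for delivering oral-stimulation training:
#' `patients x sessions x minutes-per-session x hourly wage / 60`. The
#' per-session supervision time is arm-specific (the pulsed-pacifier
#' intervention requires less hands-on delivery than manual stimulation).
#'
#' @param ps A `bia_parameters` object.
#' @param arm `"pfos"` or `"soc"`.
#' @param group `"fof"` (Markov 1 entrants) or `"non_fof"` (Markov 2).
#' @return Cost in USD.
#' @export
staff_time_cost <- function(ps, arm = c("pfos", "soc"),
                            group = c("fof", "non_fof")) {
  arm <- match.arg(tolower(arm), c("pfos", "soc"))
  group <- match.arg(group)
  split <- stratify(ps, arm)
  patients <- if (group == "fof") {
    split$masses[["nns_at_birth"]] + split$masses[["training_success"]]
  } else {
    split$masses[["training_fail"]]
  }
  sessions <- param_value(ps, "staff_sessions_per_patient")
  minutes <- param_value(ps, paste0("staff_minutes_per_session_", arm))
  wage <- param_value(ps, "staff_wage_per_hour")
  if (sessions < 0 || minutes < 0 || wage < 0) {
    stop("staffing inputs must be nonnegative", call. = FALSE)
  }
  patients * sessions * minutes * wage / 60
}

#' Attach perspective-specific costs to a cohort trace
#'
#' State-occupancy costs are exposure patient-days times the per-day unit
#' value; event costs are event tallies times the per-event unit value.
#'
#' Payer (5-year, charges): NICU level III, lower-acuity ward, in-hospital
#' infection, NGT discharge, home infection, rehospitalisation. Hospital
#' (1-year, costs): the trace is truncated at 365 days (by re-running the
#' engine from the trace's own parameter set when needed), hospital charges
#' are converted via [charge_to_cost()], NICU days are split into
#' pre-training vs training/follow-up at the training start day, and rows
#' are reported per FOF (Markov 1) and non-FOF (Markov 2) group with staff
#' time added. Lower-acuity-ward days and in-hospital infection costs fall
#' in the training/follow-up category. The total is accumulated from the
#' same category vector that is reported, so additivity is exact.
#'
#' @param trace A `bia_trace`.
#' @param ps A `bia_parameters` object (usually `trace$ps`).
#' @param persp A `bia_perspective` or perspective name.
#' @return A `bia_costs`: `data.frame(setting, group, category, amount)`
#'   plus `total`, with perspective and arm attached.
#' @export
attach_costs <- function(trace, ps = trace$ps, persp = "payer") {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  if (trace$horizon_days < persp$horizon_days) {
    stop("trace horizon (", trace$horizon_days,
         " days) shorter than the perspective horizon (",
         persp$horizon_days, ")", call. = FALSE)
  }
  v <- function(nm) param_value(ps, nm)
  if (persp$name == "payer") {
    led <- trace$ledger
    tab <- data.frame(
      setting = c(rep("In hospital", 3), rep("At home", 3)),
      group = NA_character_,
      category = c("NICU", "Lower acuity ward", "Infection",
                   "Discharged with NGT", "Infection", "Rehospitalizations"),
      amount = c(
        sum(led$nicu_pre_days + led$nicu_train_days) * v("nicu_charge_per_day"),
        sum(led$ward_days) * v("ward_charge_per_day"),
        sum(led$infections_hospital) *
          v("infection_hospital_charge_per_event"),
        sum(led$ngt_discharges) * v("ngt_discharge_charge_per_event"),
        sum(led$home_infections) * v("infection_home_cost_per_event"),
        sum(led$rehospitalizations) * v("rehosp_cost_per_event")
      ),
      stringsAsFactors = FALSE
    )
  } else {
    if (trace$horizon_days > 365) {
      trace <- run_cohort(trace$ps, trace$arm, horizon_days = 365)
    }
    ccr <- v("cost_to_charge_ratio")
    rows <- lapply(1:2, function(mk) {
      led <- trace$ledger[trace$ledger$markov == mk, ]
      grp <- if (mk == 1) "FOF group" else "Non-FOF group"
      data.frame(
        setting = "In hospital",
        group = grp,
        category = c("Pre NNS training NICU", "NNS training and follow up",
                     "Staff time for training"),
        amount = c(
          charge_to_cost(sum(led$nicu_pre_days) * v("nicu_charge_per_day"),
                         ccr),
          charge_to_cost(
            sum(led$nicu_train_days) * v("nicu_charge_per_day") +
              sum(led$ward_days) * v("ward_charge_per_day") +
              sum(led$infections_hospital) *
                v("infection_hospital_charge_per_event"), ccr),
          staff_time_cost(ps, trace$arm,
                          if (mk == 1) "fof" else "non_fof")
        ),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
  }
  if (any(is.na(tab$amount))) {
    stop("missing unit cost for category: ",
         paste(tab$category[is.na(tab$amount)], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(perspective = persp$name, arm = trace$arm, table = tab,
         total = sum(tab$amount)),
    class = "bia_costs"
  )
}

#' @export
print.bia_costs <- function(x, ...) {
  cat("<bia_costs> ", x$perspective, " perspective, arm ", x$arm, "\n",
      sep = "")
  tab <- x$table
  tab$amount <- sprintf("$%s", formatC(round(tab$amount), format = "d",
                                       big.mark = ","))
  print(tab, row.names = FALSE)
  cat(sprintf("  Total costs: $%s\n",
              formatC(round(x$total), format = "d", big.mark = ",")))
  invisible(x)
}

#' Budget impact: per-category arm differences
#'
#' Differences are reported as intervention minus comparator
#' (PFOS - SoC), so negative values are savings. The total difference is
#' accumulated from the same category differences that are reported, so the
#' difference of totals equals the total of differences exactly.
#'
#' @param b_pfos `bia_costs` for the intervention arm.
#' @param b_soc `bia_costs` for the comparator arm, same perspective.
#' @return A `bia_impact`: category table with `pfos`, `soc`, `difference`
#'   columns plus arm totals.
#' @export
compare_costs <- function(b_pfos, b_soc) {
  if (b_pfos$perspective != b_soc$perspective) {
    stop("cost breakdowns come from different perspectives", call. = FALSE)
  }
  key <- function(b) paste(b$table$setting, b$table$group, b$table$category)
  if (!identical(key(b_pfos), key(b_soc))) {
    stop("category sets do not match between arms", call. = FALSE)
  }
  tab <- b_pfos$table[c("setting", "group", "category")]
  tab$pfos <- b_pfos$table$amount
  tab$soc <- b_soc$table$amount
  tab$difference <- tab$pfos - tab$soc
  structure(
    list(perspective = b_pfos$perspective, table = tab,
         total_pfos = sum(tab$pfos), total_soc = sum(tab$soc),
         total_difference = sum(tab$difference)),
    class = "bia_impact"
  )
}

#' @export
print.bia_impact <- function(x, ...) {
  cat("<bia_impact> ", x$perspective, " perspective (PFOS - SoC)\n", sep = "")
  tab <- x$table
  for (col in c("pfos", "soc", "difference")) {
    tab[[col]] <- formatC(round(tab[[col]]), format = "d", big.mark = ",")
  }
  print(tab, row.names = FALSE)
  cat(sprintf("  Totals: PFOS $%s | SoC $%s | difference $%s\n",
              formatC(round(x$total_pfos), format = "d", big.mark = ","),
              formatC(round(x$total_soc), format = "d", big.mark = ","),
              formatC(round(x$total_difference), format = "d",
                      big.mark = ",")))
  invisible(x)
}

#' Covered insurance lives behind the modelled birth cohort
#'
#' Back-calculates the insured population that generates the modelled
#' number of preterm births per year:
#' `lives = round(n_patients / (prop_women x fertility x prop_preterm))`.
#'
#' @param ps A `bia_parameters` object.
#' @return A `bia_covered_lives` list with `lives` and its components.
#' @export
covered_lives <- function(ps) {
  pw <- param_value(ps, "prop_women_reproductive_age")
  fr <- param_value(ps, "fertility_rate_annual")
  pp <- param_value(ps, "prop_preterm_25_30")
  denom <- pw * fr * pp
  if (denom <= 0) stop("demographic denominator must be positive",
                       call. = FALSE)
  structure(
    list(lives = round(n_patients(ps) / denom),
         prop_women_reproductive_age = pw, fertility_rate_annual = fr,
         prop_preterm_25_30 = pp),
    class = "bia_covered_lives"
  )
}

#' Cost per member per month
#'
#' @param total_cost Total cost in USD over the horizon.
#' @param lives Covered lives (positive count).
#' @param months Months in the horizon (payer 5-year horizon: 60).
#' @return Full-precision USD per member-month; round to cents for display.
#' @export
pmpm <- function(total_cost, lives, months = 60) {
  if (lives <= 0 || months <= 0) {
    stop("lives and months must be positive", call. = FALSE)
  }
  total_cost / (lives * months)
}
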