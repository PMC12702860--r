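# Uncertainty apparatus: probabilistic sensitivity analysis, one-way
# (tornado) analysis, TTD sweep, device-cost threshold analysis and
# gestational-age subgroup analysis.

#' Deterministic base-case analysis
#'
#' Runs both arms at base-case parameter values under one perspective and
#' assembles the cost breakdowns, the budget impact, the clinical outcome
#' summary and (payer perspective) covered lives and per-member-per-month
#' costs.
#'
#' @param ps A `bia_parameters` object.
#' @param persp A `bia_perspective` or perspective name.
#' @return A `bia_base_result` list.
#' @export
run_base_case <- function(ps, persp = "payer") {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  tr <- lapply(c(pfos = "pfos", soc = "soc"), function(a) {
    run_cohort(ps, a, horizon_days = persp$horizon_days)
  })
  costs <- lapply(tr, attach_costs, ps = ps, persp = persp)
  impact <- compare_costs(costs$pfos, costs$soc)
  out <- list(
    perspective = persp, ps = ps, traces = tr, costs = costs,
    impact = impact,
    outcomes = list(pfos = extract_outcomes(tr$pfos, tr$soc),
                    soc = extract_outcomes(tr$soc))
  )
  if (persp$name == "payer") {
    cl <- covered_lives(ps)
    out$covered_lives <- cl
    out$pmpm <- list(pfos = pmpm(impact$total_pfos, cl$lives, 60),
                     soc = pmpm(impact$total_soc, cl$lives, 60),
                     difference = pmpm(impact$total_difference, cl$lives, 60))
  }
  structure(out, class = "bia_base_result")
}

#' @export
print.bia_base_result <- function(x, ...) {
  print(x$impact)
  if (!is.null(x$pmpm)) {
    cat(sprintf("  Covered lives %s | PMPM PFOS $%.2f, SoC $%.2f, saving $%.2f\n",
                formatC(x$covered_lives$lives, format = "d", big.mark = ","),
                x$pmpm$pfos, x$pmpm$soc, -x$pmpm$difference))
  }
  invisible(x)
}

# Total-cost difference (PFOS - SoC) for one parameter set; the workhorse
# the OWSA and TTD sweep re-evaluate.
total_cost_difference <- function(ps, persp) {
  run_base_case(ps, persp)$impact$total_difference
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws one joint parameter sample per iteration ([sample_parameters()]),
#' runs both arms on the shared draw (parameters common to the arms are
#' therefore correlated across arms by construction), and records per-
#' category and total cost differences. Summaries: mean difference, 95%
#' uncertainty interval as empirical 2.5/97.5 percentiles of the stored
#' differences (linear interpolation), and the probability of cost saving
#' (share of iterations in which the comparator arm costs more). Identical
#' master seeds reproduce identical iteration vectors. Iterations that fail
#' validation are skipped and logged; more than 1% skips aborts the run.
#'
#' @param ps A `bia_parameters` object.
#' @param persp A `bia_perspective` or perspective name.
#' @param n_iter Number of iterations (the analysis default is 5000).
#' @param seed Master seed.
#' @return A `bia_psa`: per-iteration draw table, summaries, and metadata.
#' @export
run_psa <- function(ps, persp = "payer", n_iter = 5000, seed = 1) {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  cat_key <- NULL
  rows <- vector("list", n_iter)
  skipped <- integer(0)
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      psi <- sample_parameters(ps, sub_seeds[i])
      bc <- run_base_case(psi, persp)
      imp <- bc$impact
      if (is.null(cat_key)) {
        cat_key <- paste(imp$table$group, imp$table$category)
      }
      c(total_pfos = imp$total_pfos, total_soc = imp$total_soc,
        diff_total = imp$total_difference,
        stats::setNames(imp$table$difference,
                        paste0("diff_", make.names(cat_key))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, i)
    } else {
      rows[[i]] <- res
    }
  }
  if (length(skipped) > 0.01 * n_iter) {
    stop("more than 1% of PSA iterations failed validation (",
         length(skipped), "/", n_iter, ")", call. = FALSE)
  }
  draws <- as.data.frame(do.call(rbind, rows[lengths(rows) > 0]))
  draws$iteration <- setdiff(seq_len(n_iter), skipped)
  diff <- draws$diff_total
  structure(
    list(n_iterations = n_iter, seed = seed, perspective = persp$name,
         n_patients = n_patients(ps), draws = draws,
         skipped = skipped,
         mean_difference = mean(diff),
         ui_95 = stats::quantile(diff, c(0.025, 0.975), names = FALSE,
                                 type = 7),
         prob_cost_saving = mean(diff < 0)),
    class = "bia_psa"
  )
}

#' @export
print.bia_psa <- function(x, ...) {
  cat("<bia_psa> ", x$perspective, " perspective, ", x$n_iterations,
      " iterations (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean difference $%s (95%% UI $%s; $%s)\n",
              formatC(round(x$mean_difference), format = "d", big.mark = ","),
              formatC(round(x$ui_95[1]), format = "d", big.mark = ","),
              formatC(round(x$ui_95[2]), format = "d", big.mark = ",")))
  cat(sprintf("  probability cost saving: %.1f%%\n",
              100 * x$prob_cost_saving))
  invisible(x)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-evaluates the total-cost difference with each eligible parameter in
#' turn at `value x (1 - frac)` and `value x (1 + frac)` (default +/-20%),
#' all others held at base case. Entries are ranked by the absolute spread
#' between the two results and the `top_k` widest bars are returned.
#' Parameters flagged `owsa = FALSE` in the registry (structural switches,
#' cohort size) are excluded; perturbations clamped at a bound are flagged.
#'
#' @param ps A `bia_parameters` object.
#' @param persp A `bia_perspective` or perspective name.
#' @param frac Relative perturbation (default 0.20).
#' @param top_k Number of entries reported (default 10).
#' @return A `bia_owsa` data.frame: parameter, result at low/high, spread,
#'   rank, clamping flags; base-case difference in `attr(, "base")`.
#' @export
run_owsa <- function(ps, persp = "payer", frac = 0.20, top_k = 10) {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  base <- total_cost_difference(ps, persp)
  eligible <- ps$registry$name[ps$registry$owsa]
  rows <- lapply(eligible, function(nm) {
    lo <- perturb_quiet(ps, nm, 1 - frac)
    hi <- perturb_quiet(ps, nm, 1 + frac)
    data.frame(
      parameter = nm,
      result_low = total_cost_difference(lo$ps, persp),
      result_high = total_cost_difference(hi$ps, persp),
      clamped = lo$clamped || hi$clamped,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$spread <- abs(tab$result_high - tab$result_low)
  tab <- tab[order(-tab$spread), ]
  tab$rank <- seq_len(nrow(tab))
  tab <- utils::head(tab, top_k)
  rownames(tab) <- NULL
  structure(tab, class = c("bia_owsa", "data.frame"),
            base = base, frac = frac, perspective = persp$name)
}

#' Sweep the time-to-discharge (TTD) factor
#'
#' Deterministically re-runs the model at each TTD value on the grid
#' (default 0.5 to 1.2 in steps of 0.1, around the base-case 0.8), all
#' other parameters at base case, and reports the total-cost difference
#' and its percentage change versus the base-case row.
#'
#' @param ps A `bia_parameters` object.
#' @param persp A `bia_perspective` or perspective name.
#' @param grid TTD values to evaluate.
#' @return `data.frame(ttd, difference, pct_change_vs_base)`.
#' @export
ttd_sweep <- function(ps, persp = "payer",
                      grid = seq(0.5, 1.2, by = 0.1)) {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  base_ttd <- param_value(ps, "ttd")
  base <- total_cost_difference(ps, persp)
  diffs <- vapply(grid, function(t) {
    total_cost_difference(set_parameter(ps, "ttd", t), persp)
  }, numeric(1))
  data.frame(
    ttd = grid,
    difference = diffs,
    pct_change_vs_base = 100 * (diffs - base) / abs(base),
    is_base = abs(grid - base_ttd) < 1e-12
  )
}

#' Device-cost threshold analysis
#'
#' Adds a deterministic per-patient device outlay to the intervention arm
#' of every stored PSA iteration (no re-simulation) and reports, for each
#' grid point, the probability that the intervention remains cost saving:
#' `#(iteration savings > cost x n_patients) / n_iter`. At zero device cost
#' this equals the PSA's probability of cost saving; the curve is
#' nonincreasing in the device cost by construction.
#'
#' @param psa A `bia_psa` with stored iteration-level differences.
#' @param grid Device cost per patient, USD (default $1,000-$20,000).
#' @return A `bia_threshold` data.frame: `device_cost_per_patient`,
#'   `prob_cost_saving`.
#' @export
threshold_analysis <- function(psa, grid = seq(1000, 20000, by = 1000)) {
  stopifnot(inherits(psa, "bia_psa"))
  if (length(grid) == 0) stop("empty device-cost grid", call. = FALSE)
  savings <- -psa$draws$diff_total  # SoC minus PFOS, positive = saving
  probs <- vapply(grid, function(c0) {
    mean(savings > c0 * psa$n_patients)
  }, numeric(1))
  structure(
    data.frame(device_cost_per_patient = grid, prob_cost_saving = probs),
    class = c("bia_threshold", "data.frame"),
    n_patients = psa$n_patients, n_iterations = psa$n_iterations
  )
}

#' Gestational-age subgroup analysis
#'
#' Runs the model independently on the two gestational-age subgroups
#' (25-28 and 29-30 weeks) with their own efficacy inputs and pools the
#' per-arm totals by summation. The subgroup cohort sizes must add up to
#' the reference cohort size.
#'
#' @param ps_25_28 Parameter set of the younger subgroup.
#' @param ps_29_30 Parameter set of the older subgroup.
#' @param persp A `bia_perspective` or perspective name.
#' @param n_total Required combined cohort size (default 100).
#' @return A `bia_subgroup` list: per-subgroup impacts, pooled table and
#'   totals, and the share of savings attributable to each subgroup.
#' @export
subgroup_analysis <- function(ps_25_28, ps_29_30, persp = "payer",
                              n_total = 100) {
  if (!inherits(persp, "bia_perspective")) persp <- perspective(persp)
  n1 <- n_patients(ps_25_28); n2 <- n_patients(ps_29_30)
  if (abs(n1 + n2 - n_total) > 1e-9) {
    stop("subgroup cohort sizes (", n1, " + ", n2,
         ") do not sum to ", n_total, call. = FALSE)
  }
  imp <- list(gab_25_28 = run_base_case(ps_25_28, persp)$impact,
              gab_29_30 = run_base_case(ps_29_30, persp)$impact)
  pooled_tab <- imp$gab_25_28$table
  for (col in c("pfos", "soc", "difference")) {
    pooled_tab[[col]] <- imp$gab_25_28$table[[col]] +
      imp$gab_29_30$table[[col]]
  }
  pooled <- structure(
    list(perspective = persp$name, table = pooled_tab,
         total_pfos = sum(pooled_tab$pfos),
         total_soc = sum(pooled_tab$soc),
         total_difference = sum(pooled_tab$difference)),
    class = "bia_impact"
  )
  savings <- -c(gab_25_28 = imp$gab_25_28$total_difference,
                gab_29_30 = imp$gab_29_30$total_difference)
  structure(
    list(gab_25_28 = imp$gab_25_28, gab_29_30 = imp$gab_29_30,
         pooled = pooled,
         savings_share = savings / sum(savings)),
    class = "bia_subgroup"
  )
}

#' @export
print.bia_subgroup <- function(x, ...) {
  cat("<bia_subgroup> pooled totals: PFOS $",
      formatC(round(x$pooled$total_pfos), format = "d", big.mark = ","),
      " | SoC $",
      formatC(round(x$pooled$total_soc), format = "d", big.mark = ","),
      "\n", sep = "")
  cat(sprintf("  savings share: GAB 25-28 %.1f%%, GAB 29-30 %.1f%%\n",
              100 * x$savings_share[["gab_25_28"]],
              100 * x$savings_share[["gab_29_30"]]))
  invisible(x)
}
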