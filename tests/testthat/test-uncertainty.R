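test_that("PSA runs are bit-reproducible under the same master seed", {
  a <- run_psa(PS, "payer", n_iter = 25, seed = 11)
  b <- run_psa(PS, "payer", n_iter = 25, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ui_95, b$ui_95)
  c <- run_psa(PS, "payer", n_iter = 25, seed = 12)
  expect_false(identical(a$draws$diff_total, c$draws$diff_total))
})

test_that("a fully degenerate PSA collapses onto the base case", {
  base <- nnsbia:::total_cost_difference(PS, perspective("payer"))
  psa <- run_psa(scale_uncertainty(PS, 0), "payer", n_iter = 5, seed = 3)
  expect_equal(unique(psa$draws$diff_total), base, tolerance = 1e-12)
  expect_equal(psa$ui_95, c(base, base), tolerance = 1e-12)
  expect_true(psa$prob_cost_saving %in% c(0, 1))
})

test_that("the PSA mean approaches the base case as uncertainty vanishes", {
  base <- nnsbia:::total_cost_difference(PS, perspective("payer"))
  total <- run_base_case(PS, "payer")$impact$total_soc
  for (s in c(0.05, 0.01)) {
    psa <- run_psa(scale_uncertainty(PS, s), "payer", n_iter = 120, seed = 5)
    mc_se <- stats::sd(psa$draws$diff_total) / sqrt(psa$n_iterations)
    # allowance: Monte Carlo error plus a second-order curvature term
    expect_lt(abs(psa$mean_difference - base), 4 * mc_se + 5 * s^2 * total)
  }
})

test_that("PSA summaries are order statistics of the stored draws", {
  psa <- run_psa(PS, "payer", n_iter = 40, seed = 9)
  d <- psa$draws$diff_total
  expect_equal(psa$ui_95, stats::quantile(d, c(0.025, 0.975),
                                          names = FALSE))
  expect_equal(psa$prob_cost_saving, mean(d < 0))
  expect_equal(psa$mean_difference, mean(d))
  expect_true(psa$prob_cost_saving >= 0 && psa$prob_cost_saving <= 1)
})

test_that("the tornado ranks time-to-FOF first and respects eligibility", {
  ow <- run_owsa(PS, "payer", frac = 0.20, top_k = 10)
  expect_lte(nrow(ow), 10)
  expect_equal(ow$rank, seq_len(nrow(ow)))
  expect_true(all(diff(ow$spread) <= 0))
  expect_match(ow$parameter[1], "time_to_fof")
  expect_false("n_patients" %in% ow$parameter)  # owsa = FALSE

  full <- run_owsa(PS, "payer", top_k = 999)
  # demographic inputs move only covered lives, not the cost difference
  expect_equal(full$spread[full$parameter == "prop_preterm_25_30"], 0)
  # the charge-to-cost ratio cancels in the payer view ...
  expect_equal(full$spread[full$parameter == "cost_to_charge_ratio"], 0)
  # ... but drives the hospital view
  owh <- run_owsa(PS, "hospital", top_k = 10)
  expect_true("cost_to_charge_ratio" %in% owh$parameter)
})

test_that("the TTD sweep is anchored at the base case and moves the non-FOF stay", {
  sweep <- ttd_sweep(PS, "payer")
  expect_equal(sweep$ttd, seq(0.5, 1.2, by = 0.1))
  base <- nnsbia:::total_cost_difference(PS, perspective("payer"))
  base_row <- sweep[sweep$is_base, ]
  expect_equal(base_row$difference, base, tolerance = 1e-12)
  expect_equal(base_row$pct_change_vs_base, 0, tolerance = 1e-9)

  # larger ttd -> monotonically fewer Markov 2 NICU days
  m2_days <- vapply(c(0.5, 0.8, 1.2), function(t) {
    tr <- run_cohort(set_parameter(PS, "ttd", t), "soc")
    led <- tr$ledger[tr$ledger$markov == 2, ]
    sum(led$nicu_pre_days + led$nicu_train_days)
  }, numeric(1))
  expect_true(all(diff(m2_days) < 0))
})

test_that("the threshold curve starts at the PSA probability and never rises", {
  psa <- run_psa(PS, "payer", n_iter = 60, seed = 21)
  curve <- threshold_analysis(psa, grid = c(0, seq(1000, 20000, 1000)))
  expect_equal(curve$prob_cost_saving[1], psa$prob_cost_saving)
  expect_true(all(diff(curve$prob_cost_saving) <= 0))
  # beyond every iteration's savings the probability hits zero
  sky <- threshold_analysis(psa, grid = 1e9)
  expect_equal(sky$prob_cost_saving, 0)
  expect_error(threshold_analysis(psa, grid = numeric(0)), "grid")
})

test_that("subgroup pooling is exact and matches a single run under identical inputs", {
  ps_a <- set_parameter(PS, "n_patients", 50)
  ps_b <- set_parameter(PS, "n_patients", 50)
  sub <- subgroup_analysis(ps_a, ps_b, "payer")
  expect_equal(sub$pooled$total_pfos,
               sub$gab_25_28$total_pfos + sub$gab_29_30$total_pfos)
  # occupancy is linear in cohort mass, so two identical half-cohorts pool
  # to the full cohort exactly
  full <- run_base_case(PS, "payer")$impact
  expect_equal(sub$pooled$total_soc, full$total_soc, tolerance = 1e-9)
  expect_equal(sub$pooled$total_difference, full$total_difference,
               tolerance = 1e-9)

  expect_error(subgroup_analysis(ps_a, PS, "payer"), "sum")
})

test_that("the calibrated subgroups attribute most savings to GAB 29-30", {
  sub <- subgroup_analysis(subgroup_paramset(PS, "gab_25_28"),
                           subgroup_paramset(PS, "gab_29_30"), "payer")
  expect_gt(sub$savings_share[["gab_29_30"]], 0.8)
  expect_equal(sum(sub$savings_share), 1)
  # both subgroups save under the intervention
  expect_lt(sub$gab_29_30$total_difference, 0)
})
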