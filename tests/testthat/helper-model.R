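# Shared objects, computed once per test run.

PS <- default_fixture()
TR_SOC <- run_cohort(PS, "soc")
TR_PFOS <- run_cohort(PS, "pfos")

# Parameter set built from the in-code registry with named overrides.
probe_ps <- function(...) {
  ps <- load_parameters(nnsbia:::base_registry_doc())
  overrides <- list(...)
  for (nm in names(overrides)) ps <- set_parameter(ps, nm, overrides[[nm]])
  ps
}

# Single-branch, event-free configuration with a constant daily discharge
# probability: the analytically tractable core used by several oracles.
geometric_ps <- function(p_discharge, mortality = 0) {
  probe_ps(
    prop_nns_at_birth = 1, prop_fof_fail_soc = 0, prop_fof_fail_pfos = 0,
    prop_discharge_to_ward = 0, time_to_fof_ratio_pfos = 1, ttd = 1,
    mort_hospital_daily = mortality, mort_home_annual_y1 = 0,
    mort_home_annual_later = 0, p_infection_hospital_daily = 0,
    p_infection_home_annual = 0, rehosp_rate_gab_24_27 = 0,
    rehosp_rate_gab_28_31 = 0, time_to_fof_soc = 1 / p_discharge
  )
}

# A copy of `ps` with every uncertainty fraction scaled by `s` (s = 0 makes
# the whole set degenerate for the PSA).
scale_uncertainty <- function(ps, s) {
  ps$registry$uncertainty_frac <- ps$registry$uncertainty_frac * s
  ps
}
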