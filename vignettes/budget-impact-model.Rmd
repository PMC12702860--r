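---
title: "Methods: the nnsbia budget-impact model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nnsbia budget-impact model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnsbia)
```

This vignette is the package's own account of the model: what is being
computed, which assumptions close the gaps that any cohort model of this
kind must close, and what the shipped synthetic fixture does and does not
establish.

## The decision problem

A cohort of 100 hypothetical preterm infants (gestational age at birth,
GAB, 25–30 weeks) is followed from birth for five years under two
strategies for developing non-nutritive sucking (NNS): a pulsed-pacifier
stimulation device (the intervention arm) versus manual oral stimulation
by nurses or caregivers (the comparator). The outcome is budget impact —
undiscounted total cost by care-setting category and the arm difference —
under two perspectives:

* **payer**: 5-year horizon; hospital care priced at billed charges per
  day, home events (infections, rehospitalisations) at per-event costs;
* **hospital**: 1-year horizon; charges converted to incurred costs with a
  scalar cost-to-charge ratio; home-care categories excluded; nursing time
  for training added, reported separately for the FOF and non-FOF groups.

No discounting is applied, following budget-impact convention for short
horizons. All monetary values are normalised to 2024 USD at load time
using a year-indexed inflation table
(`inst/extdata/inflation_index.csv` — a smooth ~3%/year placeholder
series, editable by the user).

## Structure

A decision tree splits each arm into three branches: NNS already developed
at birth (enters the achieved-FOF state of Markov 1 directly), training
predicted to succeed (Markov 1, pre-training state), and training
predicted to fail (Markov 2, pre-training state). The two Markov models
are structurally identical; Markov 2 represents infants discharged home
with a naso-/orogastric tube (NGT), which matters three ways: a
time-to-discharge (TTD) factor scales its discharge probability, its
dischargees are tallied (and costed) as NGT discharges, and its
home-infection probability passes through an odds ratio for tube carriers.

The 19-state space is: NICU pre-training, NICU training/follow-up,
lower-acuity ward, then {home healthy, home-managed infection,
rehospitalised} in five yearly clusters, and absorbing death. The cycle
grid is daily up to day 180 of model time and half-monthly (15 days)
thereafter to day 1825, the last cycle truncated to the horizon.

Choices the structure had to make, and why:

* **TTD functional form.** Only the direction of the effect and the
  TTD = 1 identity are given by the model's definition; we use the
  simplest monotone rule satisfying both, `p2 = min(ttd * p1, 1)`, linear
  scaling of the per-cycle discharge probability with a cap.
* **Ward stop.** Whether the lower-acuity ward precedes or substitutes
  part of the NICU stay is ambiguous; it is implemented as an optional
  post-NICU stop entered with probability `prop_discharge_to_ward` and an
  exponential stay of mean `ward_los_mean_days`. NICU-day tallies exclude
  ward days.
* **In-hospital infections** are costed tallies proportional to hospital
  exposure days (tube-days × a daily probability); they do not alter
  transitions or length of stay. Any length-of-stay effect of infection is
  absorbed into the calibrated discharge probabilities.
* **Home-managed infection** is a one-cycle transient state returning to
  home-healthy; **rehospitalisation** occupies a stay of configurable mean
  length (default 8 days) before returning home, is costed per event, and
  uses hospital mortality while in hospital.
* **Deaths** are possible from every living state: a single daily
  in-hospital probability, and year-specific annual probabilities at home.
* **Within-cycle ordering**: death takes precedence, then discharge, then
  events; the residual mass remains in state. Rows are verified
  row-stochastic to 1e-9 at construction and occupancy mass is checked for
  conservation (±1e-9) at every cycle.
* **Year clusters.** Home occupancy always lives in the cluster of the
  current model year; mass is carried forward as the grid crosses 365-day
  boundaries. The daily phase is anchored to days since birth, not days
  since NICU entry.
* **NNS at birth** is a small nonzero branch (2%) even for this very
  preterm cohort; it is exercised by tests and can be set to zero.

## Numerical choices

* **Cycle-length conversion** uses constant-hazard compounding,
  `p_cycle = 1 − (1 − p)^(L/T)` for probabilities and
  `1 − exp(−r·L/T)` for rates.
* **Person-time accrual.** Occupancy is converted to patient-days at daily
  resolution within each cycle, assuming a constant daily hazard:
  `exposure = occ · P / (1 − (1 − P)^(1/L))` for per-cycle exit
  probability `P`. Plain occupancy × length over 15-day cycles
  overstates a ~66-day mean stay by about half a day; this accrual
  reproduces the geometric closed form (mean stay `1/p`) exactly on the
  mixed grid. There is no half-cycle correction in the usual sense (no
  averaging of start- and end-of-cycle occupancy); event flows are counted
  at cycle end.
* **Hospital-perspective truncation** re-runs the engine at a 365-day
  horizon from the parameter set stored in the trace, so 1-year totals are
  exact by construction rather than prorated out of a straddling
  half-monthly cycle.
* **Degenerate inputs**: a zero cohort runs and costs to zero; zero
  uncertainty fractions make every distribution degenerate and the PSA
  collapses onto the base case.

## Parameters

Every input lives in a flat YAML registry (`default_fixture()`, or any
file via `load_parameters()`) with value, kind, reference period, value
year, uncertainty fraction, bounds and a provenance note. The ones that
matter most:

| parameter | default | units | role |
|---|---|---|---|
| `time_to_fof_soc` | ~45 (calibrated) | days | mean time from training start to discharge-eligibility, comparator |
| `time_to_fof_ratio_pfos` | ~0.87 (calibrated) | — | intervention : comparator time ratio; the treatment effect |
| `ttd` | 0.8 | — | non-FOF discharge scaling |
| `training_start_day` | 21 | days | boundary between pre-training and training NICU costs |
| `nicu_charge_per_day` | ~$3,470 (back-solved) | USD/day | dominant cost driver |
| `cost_to_charge_ratio` | 0.433 | — | hospital-perspective conversion |
| `mort_hospital_daily` | 0.0012 | /day | ~7.5% in-hospital mortality over a 66-day stay |
| `rehosp_rate_gab_24_27` / `…28_31` | 0.66 / 0.42 | /year | first-year stratum rates, mixed by `prop_gab_25_28` |

The daily discharge probability is `1 / time_to_fof` (Markov 1), times
TTD (Markov 2). Parameterising the intervention arm as a *ratio* on the
shared comparator time makes the probabilistic analysis arm-correlated:
the baseline stay cancels in the arm difference and the treatment-effect
ratio carries the decision uncertainty, which keeps the dispersion of the
simulated cost difference of the same order as the mean. Independent
per-arm draws would roughly double the spread and mostly measure baseline
uncertainty that both arms share.

## Uncertainty analyses

* **PSA** (`run_psa()`): each iteration draws every parameter once from
  its assigned distribution — gamma for costs/charges (20% relative SD),
  lognormal for odds ratios (median at the base value, log-SD = the
  uncertainty fraction), normal for continuous inputs and mid-range
  proportions (10%), beta for proportions below 0.10 or above 0.90 —
  truncated to bounds by resampling (1,000 attempts, then clamped), and
  runs both arms on the shared draw. Summaries are the mean difference,
  the empirical 2.5/97.5 percentile interval (linear interpolation) of the
  stored differences, and the probability of cost saving. Identical master
  seeds reproduce identical iteration vectors. The lognormal family is
  median-matched, deliberately; all other families are moment-matched.
* **OWSA** (`run_owsa()`): each eligible parameter at ±20%, others at
  base; entries ranked by absolute spread, top 10 reported; structural
  switches and the cohort size are flagged ineligible; clamped
  perturbations are flagged.
* **TTD sweep** (`ttd_sweep()`): deterministic re-runs over 0.5–1.2 in
  steps of 0.1.
* **Threshold analysis** (`threshold_analysis()`): a per-patient device
  outlay is added to the intervention arm of every stored PSA iteration
  (no re-simulation); the curve of the probability of remaining cost
  saving over a $1,000–$20,000 grid is nonincreasing by construction and
  anchored at the PSA's probability at zero cost.
* **Subgroups** (`subgroup_analysis()`): independent runs of the GAB 25–28
  and 29–30 parameter sets (50 + 50 infants), pooled by summation; the
  uncertainty-interval columns of rendered tables flag arm differences
  whose 95% interval excludes zero rather than reporting a p-value.

## The synthetic fixture: what it is and is not

The original input tables behind this model class are not
redistributable, so `make_default_fixture()` builds a stand-in whose
*structure* is faithful and whose headline behaviour is calibrated:

* the comparator/intervention time-to-FOF inputs are root-solved against
  the engine so the arms' mean NICU stays equal 65.8 and 59.8 days;
* training-failure proportions are solved so NGT discharges per 100 land
  near 6.4 (intervention) and 5.9 (comparator);
* the NICU daily charge is back-solved so the comparator arm's five-year
  payer outlay matches the published magnitude ($24.06M per 100 infants),
  which also places the NICU share of payer costs near 92%;
* the preterm-birth proportion is back-solved so covered lives equal
  982,791 given realistic values for the share of women of reproductive
  age (0.253) and the annual fertility rate (0.0565);
* subgroup efficacy values are solved against 81.2/80.0 (GAB 25–28) and
  50.4/39.6 (GAB 29–30) day stays, whose 50:50 mixture reproduces the
  pooled means and places roughly nine-tenths of the savings in the older
  subgroup;
* everything else (ward stay, wage, per-event costs, mortality, home-event
  rates) is a documented, realistic assumption with its provenance noted
  in the YAML.

What passing the calibration tests does **not** show: that the fixture's
individual unit values equal any source dataset's; that the arm ordering
of *home* events (infections, rehospitalisations) matches a trial — with
shared home-event inputs, the earlier-discharged intervention cohort
accrues slightly more home person-time and hence slightly more home
events, whereas arm-specific trial inputs could reverse that sign; or that
the probabilistic results generalise beyond the fixture's uncertainty
assumptions.

## Verification strategy and problem sizes

The test suite pins the model to independent oracles: the geometric
closed form for mean stay; matrix-power iteration on time-homogeneous
sub-problems (1e-10); an event-driven microsimulation of 100,000
individuals drawing every transition from the same per-cycle matrices
(agreement within 3 Monte Carlo standard errors for stays, infections,
rehospitalisations and deaths); conservation, monotonicity and
truncation identities; and exact additivity of every rendered table. The
default suite runs the probabilistic analysis at 500 iterations and
property sweeps at a handful of grid points — sizes chosen so the whole
suite completes in about two minutes on a laptop while still giving the
Monte Carlo checks resolving power; the analysis-scale default of 5,000
iterations is a function argument away.

## Known limitations

* The device's acquisition and running costs are excluded from the base
  case (the threshold analysis covers them parametrically).
* No reimbursement or revenue modelling; hospital results are cost-side
  only, and the scalar cost-to-charge ratio varies widely between
  institutions.
* No individual-level covariates, no parental quality-of-life effects, no
  neurodevelopmental outcomes: the event model is infection-centred.
* PSA draws are mutually independent beyond the shared-baseline
  correlation; no correlation structure between, say, charges and rates.
* The inflation index and several unit costs are placeholders; users with
  institutional data should replace them via the YAML registry.
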