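# nnsbia

Budget-impact modelling of oral-stimulation training to develop
non-nutritive sucking (NNS) in preterm infants.

Preterm infants (gestational age at birth 25–30 weeks) often cannot feed
orally at birth; achieving full oral feeding (FOF) is usually a
prerequisite for NICU discharge, so the speed at which NNS develops drives
length of stay — and NICU days dominate the cost of preterm care. `nnsbia`
models the care pathway of a 100-infant cohort under two NNS-training
strategies — patterned frequency-modulated oro-somatosensory stimulation
delivered by a pulsed pacifier (PFOS, the intervention) versus manual oral
stimulation (standard of care, SoC) — and computes the budget impact of
adopting the intervention from an insurance payer's and a hospital's point
of view. It is written for health-economics analysts who want a tested,
scriptable implementation of this model class rather than a spreadsheet.

## The model

A decision tree pre-stratifies each arm's cohort by predicted FOF
achievement: infants with NNS already developed at birth enter the
achieved-FOF state directly; the remainder undergo training and are routed
to **Markov 1** (training succeeds) or **Markov 2** (training fails;
discharged home with a naso-/orogastric tube, NGT). The two Markov models
share one structure over the states

> NICU (pre-training) → NICU (training & follow-up) → lower-acuity ward →
> home healthy / home-managed infection / rehospitalised → death
> (absorbing),

with home states replicated in five yearly clusters, and differ only in
their transition probabilities. Cycles are daily for the first 180 days of
model time and half-monthly thereafter, over a 5-year horizon without
discounting. Key mechanics:

- Per-period inputs are rescaled to each cycle length by constant-hazard
  conversion, `p_cycle = 1 − (1 − p)^(L/T)`.
- The non-FOF group's discharge probability is the FOF group's scaled by a
  **time-to-discharge (TTD) factor** (base case 0.8, capped at 1); TTD = 1
  makes the two models coincide.
- Rehospitalisation risk is the gestational-age-weighted mixture of the
  24–27 and 28–31 week strata, with year-specific multipliers.
- The payer perspective prices the full 5 years on hospital charges per
  day plus per-event home costs; the hospital perspective prices the first
  year only, converts charges with a scalar cost-to-charge ratio, drops
  home-care categories and adds nursing time for training, reported per
  FOF/non-FOF group.
- PMPM (per member per month) divides total cost by covered insurance
  lives — back-calculated from the share of women of reproductive age, the
  fertility rate and the preterm-birth proportion — times 60 months.

Uncertainty apparatus: 5,000-iteration (configurable) Monte Carlo PSA with
kind-specific distributions (gamma for costs/charges, lognormal for odds
ratios, normal for mid-range proportions, beta near the boundaries; 10%
relative SD for general parameters, 20% for costs), one-way ±20% tornado
analysis, a TTD sweep over 0.5–1.2, a device-cost threshold analysis
re-using the PSA draws, and a gestational-age subgroup analysis.

Because the original input tables are not redistributable, the package
ships a **calibrated synthetic fixture** (`default_fixture()`) whose
base-case run reproduces the headline calibration targets (mean NICU stay
65.8/59.8 days for SoC/PFOS, 982,791 covered lives, a ~92% NICU share of
payer costs); `make_default_fixture()` regenerates it from first
principles. See the methods vignette (`vignettes/budget-impact-model.Rmd`)
for every modelling assumption.

## Worked example

```r
library(nnsbia)

ps  <- default_fixture()
res <- run_base_case(ps, "payer")
res
#> <bia_impact> payer perspective (PFOS - SoC)
#>      setting group            category       pfos        soc difference
#>  In hospital  <NA>                NICU 20,162,490 22,185,482 -2,022,992
#>  In hospital  <NA>   Lower acuity ward     90,056     89,347        709
#>  In hospital  <NA>           Infection     16,406     18,031     -1,626
#>      At home  <NA> Discharged with NGT     24,717     22,869      1,848
#>      At home  <NA>           Infection     47,160     46,443        717
#>      At home  <NA>  Rehospitalizations  1,725,752  1,701,069     24,682
#>   Totals: PFOS $22,066,580 | SoC $24,063,242 | difference $-1,996,662
#>   Covered lives 982,791 | PMPM PFOS $0.37, SoC $0.41, saving $0.03

psa <- run_psa(ps, "payer", n_iter = 500, seed = 1)
psa
#> <bia_psa> payer perspective, 500 iterations (seed 1)
#>   mean difference $-2,003,422 (95% UI $-5,226,029; $455,241)
#>   probability cost saving: 94.8%
```

Reading the numbers: the intervention arm costs the payer about $2.0M less
per 100 infants over 5 years, almost entirely through the NICU row (the
6-day shorter mean stay × the NICU daily charge); per covered member that
is $0.37 vs $0.41 per month. The PSA says the intervention is cost saving
in ~95% of parameter draws, with a 95% uncertainty interval spanning a
small possible loss to a ~$5M saving.

Other entry points: `run_owsa()` (tornado), `ttd_sweep()`,
`threshold_analysis()`, `subgroup_analysis()` /`subgroup_paramset()`,
`render_tables()` for CSV/JSON reports, and a CLI wrapper in
`inst/cli/nnsbia` (`nnsbia base --perspective payer --out results/`).

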