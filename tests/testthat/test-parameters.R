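kind_bounds_lo <- function(kind) nnsbia:::kind_bounds(kind)[1]
kind_bounds_hi <- function(kind) nnsbia:::kind_bounds(kind)[2]

test_that("the default fixture loads as a complete validated set", {
  expect_s3_class(PS, "bia_parameters")
  expect_equal(n_patients(PS), 100)
  expect_true(all(nnsbia:::MANDATORY_PARAMS %in% PS$registry$name))
  # monetary normalisation: everything is expressed in the currency year
  mon <- PS$registry$kind %in% c("cost", "charge")
  expect_true(all(PS$registry$year_of_value[mon] == 2024))
})

test_that("validation errors name the offending parameter", {
  doc <- nnsbia:::base_registry_doc()
  is_ttd <- vapply(doc$parameters, function(p) p$name == "ttd", logical(1))

  bad <- doc
  i <- which(vapply(doc$parameters, function(p) {
    p$name == "prop_discharge_to_ward"
  }, logical(1)))
  bad$parameters[[i]]$value <- 1.2
  expect_error(load_parameters(bad), "prop_discharge_to_ward")

  missing_ttd <- doc
  missing_ttd$parameters <- doc$parameters[!is_ttd]
  expect_error(load_parameters(missing_ttd), "ttd")

  expect_error(param_value(PS, "no_such_parameter"), "no_such_parameter")
})

test_that("distribution assignment follows the kind/value rules", {
  d <- assign_distribution(0.50, "probability", 0.10)
  expect_equal(d$family, "normal")
  expect_equal(d$pars$mean, 0.50)
  expect_equal(d$pars$sd, 0.05)

  d <- assign_distribution(0.05, "probability", 0.10)
  expect_equal(d$family, "beta")
  expect_equal(d$pars$shape1 / (d$pars$shape1 + d$pars$shape2), 0.05)

  d <- assign_distribution(0.95, "probability", 0.02)
  expect_equal(d$family, "beta")

  d <- assign_distribution(1000, "cost", 0.20)
  expect_equal(d$family, "gamma")
  expect_equal(d$pars$shape, 1 / 0.2^2)
  expect_equal(d$pars$shape * d$pars$scale, 1000)
  expect_equal(sqrt(d$pars$shape) * d$pars$scale, 200)  # sd = mean * frac

  d <- assign_distribution(2.0, "odds_ratio", 0.10)
  expect_equal(d$family, "lognormal")
  expect_equal(d$pars$meanlog, log(2))

  expect_equal(assign_distribution(45, "count", 0)$family, "degenerate")
  expect_equal(assign_distribution(0, "cost", 0.2)$family, "degenerate")
  expect_error(assign_distribution(1.0, "probability", 0.1), "beta")
})

test_that("sampled moments match the assigned distributions", {
  n <- 20000
  cases <- list(
    list(value = 0.50, kind = "probability", frac = 0.10),
    list(value = 0.05, kind = "probability", frac = 0.10),
    list(value = 1000, kind = "cost", frac = 0.20),
    list(value = 45, kind = "count", frac = 0.10)
  )
  set.seed(101)
  for (cs in cases) {
    spec <- assign_distribution(cs$value, cs$kind, cs$frac)
    draws <- vapply(seq_len(n), function(i) {
      nnsbia:::sample_dist(spec, lower = kind_bounds_lo(cs$kind),
                           upper = kind_bounds_hi(cs$kind))
    }, numeric(1))
    se <- stats::sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - cs$value), 4 * se)
    expect_lt(abs(stats::sd(draws) - cs$value * cs$frac),
              0.05 * cs$value * cs$frac)
  }
  # the odds-ratio lognormal is median-matched by design
  spec <- assign_distribution(2.0, "odds_ratio", 0.10)
  draws <- vapply(seq_len(n), function(i) nnsbia:::sample_dist(spec),
                  numeric(1))
  expect_lt(abs(stats::median(draws) - 2.0), 0.02)
})

test_that("charge/cost conversion and inflation behave as definitions", {
  expect_equal(charge_to_cost(1000, 0.5), 500)
  expect_equal(charge_to_cost(0, 0.5), 0)
  expect_equal(charge_to_cost(1234.5, 1.0), 1234.5)
  expect_equal(cost_to_charge(charge_to_cost(777, 0.43), 0.43), 777)
  expect_error(charge_to_cost(100, 0), "ratio")

  idx <- data.frame(year = c(2020, 2024), index = c(100, 120))
  expect_equal(inflate_to_2024(100, 2024, idx), 100)
  expect_equal(inflate_to_2024(100, 2020, idx), 120)
  expect_error(inflate_to_2024(100, 1999, idx), "1999")
})

test_that("perturbation is local, invertible and clamps at bounds", {
  p2 <- perturb(PS, "nicu_charge_per_day", 1.2)
  expect_equal(param_value(p2, "nicu_charge_per_day"),
               1.2 * param_value(PS, "nicu_charge_per_day"))
  others <- setdiff(PS$registry$name, "nicu_charge_per_day")
  expect_equal(param_value(p2, others), param_value(PS, others))

  expect_identical(perturb(PS, "ttd", 1.0)$registry, PS$registry)
  back <- perturb(perturb(PS, "ttd", 1.25), "ttd", 1 / 1.25)
  expect_equal(param_value(back, "ttd"), param_value(PS, "ttd"))

  expect_warning(clamped <- perturb(PS, "prop_discharge_to_ward", 10),
                 "clamped")
  expect_equal(param_value(clamped, "prop_discharge_to_ward"), 1)
  expect_error(perturb(PS, "nope", 1.1), "nope")
})

test_that("joint sampling is seed-deterministic and respects bounds", {
  s1 <- sample_parameters(PS, 42)
  s2 <- sample_parameters(PS, 42)
  expect_identical(s1$registry, s2$registry)
  expect_false(identical(s1$registry$value, PS$registry$value))
  expect_silent(validate_parameters(s1))

  degenerate <- scale_uncertainty(PS, 0)
  expect_equal(sample_parameters(degenerate, 7)$registry$value,
               degenerate$registry$value)
})

test_that("the registry round-trips through CSV export/import", {
  f <- withr::local_tempfile(fileext = ".csv")
  export_parameters_csv(PS, f)
  back <- import_parameters_csv(f, meta = PS$meta)
  expect_equal(back$registry$value, PS$registry$value)
  expect_equal(back$registry$name, PS$registry$name)
})
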