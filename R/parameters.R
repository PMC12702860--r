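# Parameter registry: typed model inputs with provenance year, uncertainty
# fractions and admissible bounds, plus the sampling/perturbation machinery
# used by the sensitivity analyses.

PARAM_KINDS <- c("probability", "rate", "cost", "charge", "odds_ratio",
                 "count", "factor")

# Every parameter the cohort engine, costing layer and uncertainty module
# dereference. A set missing any of these fails validation at load time.
MANDATORY_PARAMS <- c(
  "n_patients", "prop_gab_25_28",
  "prop_nns_at_birth", "prop_fof_fail_pfos", "prop_fof_fail_soc",
  "training_start_day", "time_to_fof_soc", "time_to_fof_ratio_pfos", "ttd",
  "prop_discharge_to_ward", "ward_los_mean_days", "rehosp_los_mean_days",
  "mort_hospital_daily", "mort_home_annual_y1", "mort_home_annual_later",
  "p_infection_hospital_daily", "p_infection_home_annual",
  "or_infection_ngt_home",
  "rehosp_rate_gab_24_27", "rehosp_rate_gab_28_31",
  "rehosp_year_mult_y2", "rehosp_year_mult_y3", "rehosp_year_mult_y4",
  "rehosp_year_mult_y5",
  "nicu_charge_per_day", "ward_charge_per_day",
  "infection_hospital_charge_per_event", "ngt_discharge_charge_per_event",
  "infection_home_cost_per_event", "rehosp_cost_per_event",
  "cost_to_charge_ratio",
  "staff_wage_per_hour", "staff_sessions_per_patient",
  "staff_minutes_per_session_pfos", "staff_minutes_per_session_soc",
  "prop_women_reproductive_age", "fertility_rate_annual",
  "prop_preterm_25_30"
)

default_uncertainty_frac <- function(kind) {
  ifelse(kind %in% c("cost", "charge"), 0.20, 0.10)
}

kind_bounds <- function(kind) {
  switch(kind,
    probability = c(0, 1),
    rate        = c(0, Inf),
    cost        = c(0, Inf),
    charge      = c(0, Inf),
    odds_ratio  = c(1e-12, Inf),
    count       = c(0, Inf),
    factor      = c(-Inf, Inf)
  )
}

#' Load and validate a model parameter set
#'
#' Reads a flat structured parameter file (YAML, one document) holding the
#' complete input registry for the budget-impact model: decision-tree
#' proportions, per-period event probabilities and rates, unit charges/costs
#' with their value year, staffing inputs and the demographic inputs used to
#' back-calculate covered insurance lives. Monetary values carrying a
#' `year_of_value` earlier than the currency year are inflated on load using
#' the packaged inflation index (or one supplied via `index`), so a validated
#' set is always expressed in 2024 USD. Charge-kind inputs keep their kind
#' tag so the hospital perspective can convert them with the cost-to-charge
#' ratio later.
#'
#' @param source Path to a YAML parameter file, or an already-parsed list
#'   with elements `meta` and `parameters`.
#' @param index Optional inflation index `data.frame(year, index)`; defaults
#'   to the table shipped with the package.
#' @return A validated `bia_parameters` object: a registry `data.frame`
#'   (name, value, kind, period_days, year_of_value, uncertainty_frac,
#'   lower, upper, owsa, note) plus metadata (`currency_year`, `label`).
#' @export
#' @examples
#' ps <- default_fixture()
#' param_value(ps, "ttd")
load_parameters <- function(source, index = NULL) {
  doc <- if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      stop("parameter file not found: ", source, call. = FALSE)
    }
    yaml::read_yaml(source)
  } else if (is.list(source)) {
    source
  } else {
    stop("`source` must be a file path or a parsed list", call. = FALSE)
  }
  if (is.null(doc$parameters)) {
    stop("parameter document has no `parameters` section", call. = FALSE)
  }
  meta <- doc$meta %||% list()
  currency_year <- meta$currency_year %||% 2024

  rows <- lapply(doc$parameters, function(p) {
    if (is.null(p$name) || is.null(p$value) || is.null(p$kind)) {
      stop("each parameter needs at least `name`, `value`, `kind`",
           call. = FALSE)
    }
    kind <- match.arg(p$kind, PARAM_KINDS)
    kb <- kind_bounds(kind)
    data.frame(
      name = p$name,
      value = as.numeric(p$value),
      kind = kind,
      period_days = as.numeric(p$period_days %||% NA_real_),
      year_of_value = as.numeric(p$year_of_value %||%
        if (kind %in% c("cost", "charge")) currency_year else NA_real_),
      uncertainty_frac = as.numeric(p$uncertainty_frac %||%
        default_uncertainty_frac(kind)),
      lower = as.numeric(p$lower %||% kb[1]),
      upper = as.numeric(p$upper %||% kb[2]),
      owsa = isTRUE(p$owsa %||% TRUE),
      note = as.character(p$note %||% ""),
      stringsAsFactors = FALSE
    )
  })
  registry <- do.call(rbind, rows)
  if (anyDuplicated(registry$name)) {
    stop("duplicate parameter names: ",
         paste(unique(registry$name[duplicated(registry$name)]),
               collapse = ", "), call. = FALSE)
  }

  ps <- structure(
    list(registry = registry,
         meta = list(currency_year = currency_year,
                     label = meta$label %||% "unnamed parameter set")),
    class = "bia_parameters"
  )
  ps <- normalize_currency(ps, index)
  validate_parameters(ps)
  ps
}

normalize_currency <- function(ps, index = NULL) {
  if (is.null(index)) index <- load_inflation_index()
  reg <- ps$registry
  cy <- ps$meta$currency_year
  monetary <- reg$kind %in% c("cost", "charge")
  stale <- monetary & !is.na(reg$year_of_value) & reg$year_of_value != cy
  for (i in which(stale)) {
    reg$value[i] <- inflate_to_2024(reg$value[i], reg$year_of_value[i], index)
    reg$year_of_value[i] <- cy
  }
  ps$registry <- reg
  ps
}

#' @export
print.bia_parameters <- function(x, ...) {
  cat("<bia_parameters> ", x$meta$label, "\n", sep = "")
  cat("  ", nrow(x$registry), " parameters, currency year ",
      x$meta$currency_year, "\n", sep = "")
  cat("  cohort size: ", param_value(x, "n_patients"), "\n", sep = "")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks that all mandatory parameters are present, that every value lies
#' inside both its kind-level bounds (probabilities in \[0, 1\], monetary
#' values nonnegative, odds ratios positive) and its parameter-level bounds,
#' and that uncertainty fractions are nonnegative. Errors name the offending
#' parameter.
#'
#' @param ps A `bia_parameters` object.
#' @return `ps`, invisibly, if valid.
#' @export
validate_parameters <- function(ps) {
  stopifnot(inherits(ps, "bia_parameters"))
  reg <- ps$registry
  missing <- setdiff(MANDATORY_PARAMS, reg$name)
  if (length(missing) > 0) {
    stop("missing mandatory parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    kb <- kind_bounds(reg$kind[i])
    lo <- max(reg$lower[i], kb[1])
    hi <- min(reg$upper[i], kb[2])
    v <- reg$value[i]
    if (!is.finite(v) || v < lo || v > hi) {
      stop(sprintf("parameter '%s' value %g outside bounds [%g, %g]",
                   reg$name[i], v, lo, hi), call. = FALSE)
    }
    if (reg$uncertainty_frac[i] < 0) {
      stop(sprintf("parameter '%s' has negative uncertainty_frac",
                   reg$name[i]), call. = FALSE)
    }
  }
  invisible(ps)
}

#' Look up a parameter value
#'
#' @param ps A `bia_parameters` object.
#' @param name Parameter name.
#' @return The numeric base value.
#' @export
param_value <- function(ps, name) {
  i <- match(name, ps$registry$name)
  if (any(is.na(i))) {
    stop("unknown parameter(s): ",
         paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  ps$registry$value[i]
}

#' Replace a parameter value (with validation)
#'
#' @param ps A `bia_parameters` object.
#' @param name Parameter name.
#' @param value New value; must respect the parameter's bounds.
#' @return The modified parameter set.
#' @export
set_parameter <- function(ps, name, value) {
  i <- match(name, ps$registry$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  ps$registry$value[i] <- value
  validate_parameters(ps)
  ps
}

#' Number of patients in the modelled cohort
#' @param ps A `bia_parameters` object.
#' @return Cohort size (the model's default is 100 hypothetical infants).
#' @export
n_patients <- function(ps) param_value(ps, "n_patients")

#' Assign a sampling distribution to a parameter
#'
#' Implements the distribution-assignment rules used by the probabilistic
#' sensitivity analysis: gamma for costs and charges, lognormal for odds
#' ratios (median at the base value, log-scale SD equal to the uncertainty
#' fraction), normal for mid-range proportions (base value in \[0.10, 0.90\])
#' and other continuous inputs, and beta for proportions near the boundaries
#' (< 0.10 or > 0.90). A zero uncertainty fraction yields a degenerate
#' distribution that always returns the base value. Moments are matched so
#' the sampled mean equals the base value and the standard deviation equals
#' `value * uncertainty_frac` (for the lognormal, the median is matched).
#'
#' @param value Base value.
#' @param kind Parameter kind (one of `r paste(PARAM_KINDS, collapse = ", ")`).
#' @param uncertainty_frac Relative standard deviation.
#' @return A `bia_dist` object: `list(family, pars)`.
#' @export
#' @examples
#' assign_distribution(0.5, "probability", 0.10)   # normal(0.5, 0.05)
#' assign_distribution(1000, "cost", 0.20)         # gamma, mean 1000, sd 200
assign_distribution <- function(value, kind = "factor",
                                uncertainty_frac = NULL) {
  if (inherits(value, "bia_parameters")) {
    stop("pass a scalar value, not a parameter set", call. = FALSE)
  }
  kind <- match.arg(kind, PARAM_KINDS)
  if (is.null(uncertainty_frac)) {
    uncertainty_frac <- default_uncertainty_frac(kind)
  }
  frac <- uncertainty_frac
  dist <- function(family, pars) {
    structure(list(family = family, pars = pars, mean = value),
              class = "bia_dist")
  }
  if (frac == 0 || value == 0) return(dist("degenerate", list(value = value)))
  sd <- abs(value) * frac
  if (kind %in% c("cost", "charge")) {
    shape <- 1 / frac^2
    return(dist("gamma", list(shape = shape, scale = value / shape)))
  }
  if (kind == "odds_ratio") {
    if (value <= 0) stop("odds ratio must be positive", call. = FALSE)
    return(dist("lognormal", list(meanlog = log(value), sdlog = frac)))
  }
  if (kind == "probability" && (value < 0.10 || value > 0.90)) {
    if (value <= 0 || value >= 1) {
      stop("beta distribution requires a value in (0, 1); got ", value,
           call. = FALSE)
    }
    v <- sd^2
    vmax <- value * (1 - value)
    if (v >= vmax) v <- 0.99 * vmax  # keep the beta proper
    k <- vmax / v - 1
    return(dist("beta", list(shape1 = value * k, shape2 = (1 - value) * k)))
  }
  dist("normal", list(mean = value, sd = sd))
}

# One draw from a bia_dist, truncated to [lower, upper] by resampling
# (max 1000 attempts, then clamped). Consumes RNG state.
sample_dist <- function(spec, lower = -Inf, upper = Inf) {
  draw1 <- function() {
    switch(spec$family,
      degenerate = spec$pars$value,
      normal = stats::rnorm(1, spec$pars$mean, spec$pars$sd),
      beta = stats::rbeta(1, spec$pars$shape1, spec$pars$shape2),
      gamma = stats::rgamma(1, shape = spec$pars$shape,
                            scale = spec$pars$scale),
      lognormal = stats::rlnorm(1, spec$pars$meanlog, spec$pars$sdlog)
    )
  }
  x <- draw1()
  tries <- 0
  while ((x < lower || x > upper) && tries < 1000) {
    x <- draw1()
    tries <- tries + 1
  }
  min(max(x, lower), upper)
}

#' Convert a billed charge into an incurred cost
#'
#' Applies a scalar cost-to-charge ratio (defined as cost / charge, so
#' typically below 1) to estimate hospital costs from billed charges.
#'
#' @param charge Nonnegative charge in USD.
#' @param ratio Positive cost-to-charge ratio.
#' @return `charge * ratio`.
#' @seealso [cost_to_charge()] for the inverse.
#' @export
charge_to_cost <- function(charge, ratio) {
  if (any(ratio <= 0)) stop("cost-to-charge ratio must be > 0", call. = FALSE)
  if (any(charge < 0)) stop("charge must be >= 0", call. = FALSE)
  charge * ratio
}

#' @rdname charge_to_cost
#' @param cost Nonnegative cost in USD.
#' @export
cost_to_charge <- function(cost, ratio) {
  if (any(ratio <= 0)) stop("cost-to-charge ratio must be > 0", call. = FALSE)
  if (any(cost < 0)) stop("cost must be >= 0", call. = FALSE)
  cost / ratio
}

#' Load the packaged inflation index table
#'
#' A small editable year-indexed medical-price series used to express all
#' monetary inputs in the model's 2024 currency year. The shipped values are
#' a smooth placeholder series (roughly 3% annual growth), not an official
#' statistic; users with access to a preferred index can pass their own
#' table to [load_parameters()] or [inflate_to_2024()].
#'
#' @param path Optional path to an alternative CSV with columns
#'   `year, index`.
#' @return `data.frame(year, index)`.
#' @export
load_inflation_index <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "inflation_index.csv", package = "nnsbia")
  }
  idx <- utils::read.csv(path)
  stopifnot(all(c("year", "index") %in% names(idx)))
  idx
}

#' Inflate a monetary value to 2024 USD
#'
#' @param value Amount in USD of `year_of_value`.
#' @param year_of_value Calendar year the amount refers to.
#' @param index Inflation index table `data.frame(year, index)`.
#' @return `value * index(2024) / index(year_of_value)`.
#' @export
inflate_to_2024 <- function(value, year_of_value,
                            index = load_inflation_index()) {
  for (y in c(year_of_value, 2024)) {
    if (!(y %in% index$year)) {
      stop("year ", y, " not present in the inflation index", call. = FALSE)
    }
  }
  value * index$index[index$year == 2024] /
    index$index[index$year == year_of_value]
}

#' Perturb one parameter by a multiplicative factor
#'
#' Used by the one-way sensitivity analysis (base case times 0.8 and 1.2).
#' The perturbed value is clamped to the parameter's admissible bounds with
#' a warning; all other parameters are untouched.
#'
#' @param ps A `bia_parameters` object.
#' @param name Parameter to scale.
#' @param factor Multiplicative factor.
#' @return A modified copy of `ps`.
#' @export
perturb <- function(ps, name, factor) {
  res <- perturb_quiet(ps, name, factor)
  if (res$clamped) {
    warning("perturbed value for '", name, "' clamped to its bounds",
            call. = FALSE)
  }
  res$ps
}

perturb_quiet <- function(ps, name, factor) {
  i <- match(name, ps$registry$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  reg <- ps$registry
  kb <- kind_bounds(reg$kind[i])
  lo <- max(reg$lower[i], kb[1])
  hi <- min(reg$upper[i], kb[2])
  v <- reg$value[i] * factor
  clamped <- v < lo || v > hi
  reg$value[i] <- min(max(v, lo), hi)
  ps$registry <- reg
  list(ps = ps, clamped = clamped)
}

#' Draw one joint Monte Carlo sample of the parameter set
#'
#' Every parameter is drawn independently from the distribution assigned by
#' [assign_distribution()], truncated to its bounds by resampling (up to
#' 1000 attempts, then clamped). Parameters with a zero uncertainty fraction
#' are returned unchanged. Identical seeds produce identical draws.
#'
#' @param ps A `bia_parameters` object.
#' @param seed Integer seed for the draw.
#' @return A `bia_parameters` object with sampled values.
#' @export
sample_parameters <- function(ps, seed) {
  set.seed(seed)
  reg <- ps$registry
  for (i in seq_len(nrow(reg))) {
    spec <- assign_distribution(reg$value[i], reg$kind[i],
                                reg$uncertainty_frac[i])
    if (spec$family == "degenerate") next
    kb <- kind_bounds(reg$kind[i])
    reg$value[i] <- sample_dist(spec,
                                lower = max(reg$lower[i], kb[1]),
                                upper = min(reg$upper[i], kb[2]))
  }
  ps$registry <- reg
  ps
}

#' Export / import the parameter registry as CSV (for auditing)
#'
#' @param ps A `bia_parameters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters_csv <- function(ps, path) {
  utils::write.csv(ps$registry, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_parameters_csv
#' @param meta Optional metadata list (`currency_year`, `label`) attached to
#'   the imported set.
#' @export
import_parameters_csv <- function(path, meta = list()) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  doc <- list(
    meta = meta,
    parameters = lapply(seq_len(nrow(reg)), function(i) as.list(reg[i, ]))
  )
  load_parameters(doc)
}

# Stable content hash of a parameter set, embedded in report artifacts.
param_hash <- function(ps) {
  rlang::hash(list(ps$registry, ps$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
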