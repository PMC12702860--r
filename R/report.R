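# Report rendering: table-shaped CSV/JSON artifacts with full-precision
# values (monetary rounding happens only at display), provenance metadata
# embedded in every JSON artifact, and the tornado/threshold figures.

artifact_provenance <- function(ps, seed = NULL) {
  list(package_version = as.character(utils::packageVersion("nnsbia")),
       parameter_hash = param_hash(ps),
       seed = seed)
}

# Full-precision numeric CSV writer: numbers are serialised with enough
# digits to round-trip exactly, so sums over a re-read table match the
# written total bit for bit.
write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- do.call(cbind, cols)
  utils::write.table(rbind(names(df), out), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, qmethod = "double")
  invisible(path)
}

impact_to_table <- function(impact) {
  tab <- impact$table
  total <- data.frame(setting = "", group = "", category = "Total costs",
                      pfos = impact$total_pfos, soc = impact$total_soc,
                      difference = impact$total_difference,
                      stringsAsFactors = FALSE)
  tab$group[is.na(tab$group)] <- ""
  rbind(tab, total)
}

clinical_table <- function(result) {
  op <- result$outcomes$pfos; os <- result$outcomes$soc
  rows <- data.frame(
    setting = c("In hospital", "In hospital", "At home", "At home",
                "At home"),
    category = c("NICU days (in days)", "Number of infections due to NGT",
                 "Discharged with NGT (number of patients)",
                 "Number of infections", "Number of rehospitalizations"),
    pfos = c(op$nicu_days, op$infections_hospital, op$ngt_discharges,
             op$home_infections, op$rehospitalizations),
    soc = c(os$nicu_days, os$infections_hospital, os$ngt_discharges,
            os$home_infections, os$rehospitalizations),
    stringsAsFactors = FALSE
  )
  rows$difference <- rows$pfos - rows$soc
  rows
}

#' Render result tables to CSV and JSON
#'
#' Writes the cost table (care-setting rows for the payer perspective;
#' FOF-group rows for the hospital perspective) with a total row that is
#' the exact sum of the rendered full-precision category values, plus a
#' clinical outcome table, in CSV and/or JSON. JSON artifacts embed the
#' package version, the parameter-set hash and the seed, so runs can be
#' reproduced. Existing files are not overwritten unless `overwrite = TRUE`.
#'
#' @param result A `bia_base_result` (from [run_base_case()]).
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"json"` or both.
#' @param seed Seed recorded in the artifacts (if any randomness upstream).
#' @param overwrite Allow replacing existing files.
#' @return Character vector of the files written, invisibly.
#' @export
render_tables <- function(result, dir, format = c("csv", "json"),
                          seed = NULL, overwrite = FALSE) {
  stopifnot(inherits(result, "bia_base_result"))
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  persp <- result$perspective$name
  tabs <- list(costs = impact_to_table(result$impact),
               clinical = clinical_table(result))
  files <- character(0)
  for (nm in names(tabs)) {
    base <- file.path(dir, paste0(nm, "_", persp))
    if ("csv" %in% format) {
      f <- paste0(base, ".csv")
      if (file.exists(f) && !overwrite) {
        stop("refusing to overwrite ", f, " (use overwrite = TRUE)",
             call. = FALSE)
      }
      write_csv_exact(tabs[[nm]], f)
      files <- c(files, f)
    }
    if ("json" %in% format) {
      f <- paste0(base, ".json")
      if (file.exists(f) && !overwrite) {
        stop("refusing to overwrite ", f, " (use overwrite = TRUE)",
             call. = FALSE)
      }
      payload <- list(perspective = persp, table = tabs[[nm]],
                      provenance = artifact_provenance(result$ps, seed))
      if (nm == "costs" && !is.null(result$pmpm)) {
        payload$covered_lives <- result$covered_lives$lives
        payload$pmpm <- result$pmpm
      }
      jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = I(17),
                           dataframe = "rows")
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Export a cohort trace as long-format CSV
#'
#' One row per (cycle, markov, state) with the end-of-cycle occupancy
#' mass; deterministic column order.
#'
#' @param trace A `bia_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  rows <- lapply(1:2, function(mk) {
    occ <- trace$occupancy[[mk]]
    data.frame(
      cycle = rep(trace$grid$cycle, times = ncol(occ)),
      arm = trace$arm,
      markov = mk,
      state = rep(colnames(occ), each = nrow(occ)),
      mass = as.vector(occ),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$markov, df$cycle, match(df$state, state_names())), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param owsa A `bia_owsa` (from [run_owsa()]).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa) {
  stopifnot(inherits(owsa, "bia_owsa"))
  base <- attr(owsa, "base")
  df <- as.data.frame(owsa)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df$result_low, df$result_high)
  df$hi <- pmax(df$result_low, df$result_high)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(
      x = "Total cost difference, intervention - comparator (USD)",
      y = NULL,
      title = sprintf("One-way sensitivity analysis (%s perspective)",
                      attr(owsa, "perspective"))) +
    ggplot2::theme_minimal()
}

#' Threshold curve: probability of cost saving vs device cost
#'
#' @param curve A `bia_threshold` (from [threshold_analysis()]).
#' @return A ggplot object.
#' @export
plot_threshold <- function(curve) {
  stopifnot(inherits(curve, "bia_threshold"))
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$device_cost_per_patient,
                               y = .data$prob_cost_saving)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Device cost per patient (USD)",
                  y = "Probability of cost saving") +
    ggplot2::theme_minimal()
}
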