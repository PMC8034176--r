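# Configuration reading and result writing. Configuration is structured
# YAML with sections profiles / schedules / case_mix / labor / scenario;
# results are comma-delimited tables with a one-line schema header plus a
# human-readable text report.

CONFIG_SCHEMA <- "sccapacity-config-v1"
RESULTS_SCHEMA <- "sccapacity-results-v1"

#' Read a model configuration file
#'
#' Parses a YAML configuration holding the per-cycle stage times
#' (`profiles`), yearly regimen schedules and case mix per drug, and
#' optional `labor` and `scenario` sections, and validates everything into
#' domain objects. Parse failures, missing sections and invariant violations
#' raise distinct condition classes (`sccapacity_parse_error`,
#' `sccapacity_config_error`, `sccapacity_invariant_error`).
#'
#' @param path Path to a YAML configuration file. The packaged reference
#'   configuration is at
#'   `system.file("extdata", "reference_inputs.yaml", package = "sccapacity")`.
#' @return List with elements `profiles` ([cycle_profiles()]), `schedules`
#'   and `case_mix` (named per-drug lists of [regimen_schedules()] /
#'   [case_mix()]), `labor` ([labor_cost_model()]) and `scenario_mode`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file does not exist: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_parse("cannot parse config ", path, ": ", conditionMessage(e))
  })
  for (sec in c("profiles", "schedules", "case_mix")) {
    if (is.null(raw[[sec]])) {
      stop_config("config is missing required section [", sec, "]")
    }
  }
  to_df <- function(rows, section) {
    if (!length(rows)) stop_config("section [", section, "] is empty")
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  profiles <- cycle_profiles(to_df(raw$profiles, "profiles"))

  sched_df <- to_df(raw$schedules, "schedules")
  mix_df <- to_df(raw$case_mix, "case_mix")
  if (is.null(sched_df$drug) || is.null(mix_df$drug)) {
    stop_config("schedules and case_mix entries must name their drug")
  }
  schedules <- lapply(split(sched_df, sched_df$drug), function(g) {
    regimen_schedules(g[setdiff(names(g), "drug")])
  })
  mixes <- lapply(split(mix_df, mix_df$drug), function(g) {
    case_mix(g[setdiff(names(g), "drug")])
  })
  for (d in names(mixes)) {
    if (is.null(schedules[[d]])) {
      stop_config("case mix given for ", d, " but no schedules")
    }
  }

  labor <- if (is.null(raw$labor)) labor_cost_model() else {
    labor_cost_model(raw$labor$annual_gross_salary_eur,
                     raw$labor$working_hours_per_month,
                     raw$labor$cost_per_minute_eur)
  }
  mode <- if (is.null(raw$scenario$mode)) "current" else raw$scenario$mode
  if (!mode %in% c("current", "max", "both")) {
    stop_config("scenario mode must be current, max or both, got ", mode)
  }
  list(profiles = profiles, schedules = schedules, case_mix = mixes,
       labor = labor, scenario_mode = mode)
}

#' Write a model configuration file
#'
#' Inverse of [read_config()]: serializes profiles, schedules and case mix
#' (plus optional labor and scenario sections) back to YAML. Reading the
#' written file reproduces the inputs.
#'
#' @param inputs A list shaped like the return value of [read_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(inputs, path) {
  df_rows <- function(df) lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
  with_drug <- function(lst) {
    out <- list()
    for (d in names(lst)) {
      df <- as.data.frame(lst[[d]])
      df <- cbind(drug = d, df)
      out <- c(out, df_rows(df))
    }
    out
  }
  doc <- list(schema = CONFIG_SCHEMA,
              profiles = df_rows(as.data.frame(inputs$profiles)),
              schedules = with_drug(inputs$schedules),
              case_mix = with_drug(inputs$case_mix))
  if (!is.null(inputs$labor)) {
    doc$labor <- Filter(Negate(is.null), unclass(inputs$labor))
  }
  if (!is.null(inputs$scenario_mode)) {
    doc$scenario <- list(mode = inputs$scenario_mode)
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))

write_schema_csv <- function(df, path, schema = RESULTS_SCHEMA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", schema), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write hospital results to delimited tables and a text report
#'
#' Emits `per_hospital.csv` (one row per hospital and parameter),
#' `aggregate.csv` (mean percentage variation per parameter) and
#' `report.txt` (monthly patient-time table by drug and route, and the
#' aggregate parameter summary). Percentages and euro values are written to
#' two decimals, times as integers; output is deterministic for fixed
#' inputs.
#'
#' @param results List of `hospital_result` objects (may be empty: tables
#'   are then headers-only).
#' @param out_dir Output directory (created if needed).
#' @param profiles Cycle profiles used for the report's monthly-time table.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir,
                          profiles = reference_cycle_times()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) stop_config("cannot create output directory ", out_dir)

  empty_long <- data.frame(hospital_id = character(), parameter = character(),
                           value = character(), units = character())
  long <- if (length(results)) {
    x <- do.call(rbind, lapply(results, `[[`, "table"))
    x$value <- fmt2(x$value)
    x
  } else empty_long
  f1 <- file.path(out_dir, "per_hospital.csv")
  write_schema_csv(long, f1)

  agg <- if (length(results)) {
    a <- aggregate_hospitals(results)
    a$mean_value <- fmt2(a$mean_value)
    a
  } else {
    data.frame(parameter = character(), mean_value = character(),
               units = character(), n_hospitals = integer())
  }
  f2 <- file.path(out_dir, "aggregate.csv")
  write_schema_csv(agg, f2)

  f3 <- file.path(out_dir, "report.txt")
  con <- file(f3, open = "wt")
  writeLines(paste0("# ", RESULTS_SCHEMA, " report"), con)
  writeLines("", con)
  writeLines("Monthly patient time in hospital (minutes, rounded per stage)",
             con)
  mt <- reference_monthly_times(profiles)
  mt$total_unrounded <- NULL
  writeLines(utils::capture.output(print(mt, row.names = FALSE)), con)
  writeLines("", con)
  if (nrow(agg)) {
    writeLines(sprintf("Aggregate over %d hospital(s): mean percentage variation",
                       length(results)), con)
    writeLines(utils::capture.output(print(agg, row.names = FALSE)), con)
  } else {
    writeLines("No hospital results.", con)
  }
  close(con)
  invisible(c(f1, f2, f3))
}
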