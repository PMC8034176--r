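#' @keywords internal
"_PACKAGE"

# Stage labels used throughout: patient time is decomposed into waiting room,
# administration chair and medical consultation minutes.
STAGES <- c("waiting_min", "chair_min", "consultation_min")

DRUGS <- c("rituximab", "trastuzumab")
ROUTES <- c("IV", "SC")
PHASES <- c("loading_combo", "combo", "maintenance")

#' Per-visit stage times
#'
#' Bundle of the three patient-time components of a single treatment visit:
#' minutes in the waiting room, minutes occupying an administration chair,
#' and minutes of medical consultation.
#'
#' @param waiting_min,chair_min,consultation_min Non-negative finite minutes.
#' @return A named numeric vector of class `stage_times` with components
#'   `waiting_min`, `chair_min`, `consultation_min`.
#' @examples
#' st <- stage_times(71, 296, 20)
#' cycle_total(st)
#' @export
stage_times <- function(waiting_min, chair_min, consultation_min) {
  x <- c(waiting_min = waiting_min, chair_min = chair_min,
         consultation_min = consultation_min)
  if (!is.numeric(x) || length(x) != 3L) {
    stop_invariant("stage times must be three numeric values")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_invariant("stage times must be non-negative and finite, got (",
                   paste(x, collapse = ", "), ")")
  }
  structure(x, class = "stage_times")
}

#' Total visit time
#'
#' Total patient minutes for one cycle: the exact sum of waiting, chair and
#' consultation components.
#'
#' @param st A [stage_times()] object (or a non-negative numeric vector of
#'   length 3).
#' @return Total minutes (scalar).
#' @export
cycle_total <- function(st) {
  if (!inherits(st, "stage_times")) {
    st <- stage_times(st[[1L]], st[[2L]], st[[3L]])
  }
  sum(unclass(st))
}

#' Per-cycle time profiles for drug, route and treatment phase
#'
#' A profile table holds the stage times of one visit for each combination of
#' drug (rituximab, trastuzumab), route (IV, SC) and phase. Phases are
#' `combo` (cycle in combination with chemotherapy), `maintenance`
#' (monotherapy maintenance cycle) and, for trastuzumab only, `loading_combo`
#' (the first cycle, which for the IV route includes the loading dose).
#'
#' @param df A data frame with columns `drug`, `route`, `phase`,
#'   `waiting_min`, `chair_min`, `consultation_min`.
#' @return The validated data frame, classed `cycle_profiles`.
#' @seealso [reference_cycle_times()] for the packaged study values.
#' @export
cycle_profiles <- function(df) {
  needed <- c("drug", "route", "phase", STAGES)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_invariant("profile table lacks columns: ",
                   paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[needed]
  if (!all(df$drug %in% DRUGS)) stop_invariant("unknown drug in profiles")
  if (!all(df$route %in% ROUTES)) stop_invariant("unknown route in profiles")
  if (!all(df$phase %in% PHASES)) stop_invariant("unknown phase in profiles")
  if (any(df$phase == "loading_combo" & df$drug != "trastuzumab")) {
    stop_invariant("loading_combo profiles are defined for trastuzumab only")
  }
  key <- paste(df$drug, df$route, df$phase)
  if (anyDuplicated(key)) {
    stop_invariant("duplicate profile for ", key[duplicated(key)][1L])
  }
  for (s in STAGES) {
    if (any(!is.finite(df[[s]])) || any(df[[s]] < 0)) {
      stop_invariant("profile stage times must be non-negative and finite")
    }
  }
  structure(df, class = c("cycle_profiles", "data.frame"))
}

# Look up one profile row; configuration error names the missing triple.
lookup_profile <- function(profiles, drug, route, phase) {
  i <- which(profiles$drug == drug & profiles$route == route &
             profiles$phase == phase)
  if (length(i) != 1L) {
    stop_config("no cycle-time profile for (", drug, ", ", route, ", ",
                phase, ")")
  }
  st <- as.numeric(profiles[i, STAGES])
  names(st) <- STAGES
  st
}

#' Yearly regimen schedules
#'
#' One row per indication: how many cycles per year are given in each phase.
#' `n_loading_cycles` is 0 or 1 (trastuzumab's first cycle carries the IV
#' loading dose); `n_combo_cycles` excludes it. `first_cycle_always_iv`
#' marks regimens whose first dose is administered IV even on the SC pathway
#' (all rituximab indications).
#'
#' @param df Data frame with columns `indication_id`, `n_loading_cycles`,
#'   `n_combo_cycles`, `n_maintenance_cycles`, `first_cycle_always_iv`.
#' @return Validated data frame classed `regimen_schedules`.
#' @export
regimen_schedules <- function(df) {
  needed <- c("indication_id", "n_loading_cycles", "n_combo_cycles",
              "n_maintenance_cycles", "first_cycle_always_iv")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_invariant("schedule table lacks columns: ",
                   paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[needed]
  cnt <- c("n_loading_cycles", "n_combo_cycles", "n_maintenance_cycles")
  for (cc in cnt) {
    if (any(df[[cc]] < 0) || any(df[[cc]] != round(df[[cc]]))) {
      stop_invariant(cc, " must be a non-negative integer count")
    }
  }
  if (any(!df$n_loading_cycles %in% c(0, 1))) {
    stop_invariant("n_loading_cycles must be 0 or 1")
  }
  if (anyDuplicated(df$indication_id)) {
    stop_invariant("indication_id values must be unique")
  }
  structure(df, class = c("regimen_schedules", "data.frame"))
}

#' Case mix across indications
#'
#' Population shares per indication, used to weight per-indication annual
#' times. Shares must lie in \[0, 1\] and sum to 1 (tolerance 1e-9).
#'
#' @param df Data frame with columns `indication_id`, `share`.
#' @return Validated data frame classed `case_mix`.
#' @export
case_mix <- function(df) {
  needed <- c("indication_id", "share")
  if (!all(needed %in% names(df))) {
    stop_invariant("case mix needs columns indication_id, share")
  }
  df <- as.data.frame(df)[needed]
  if (any(df$share < 0) || any(df$share > 1)) {
    stop_invariant("case-mix shares must lie in [0, 1]")
  }
  if (abs(sum(df$share) - 1) > 1e-9) {
    stop_invariant("case-mix shares must sum to 1, got ", sum(df$share))
  }
  if (anyDuplicated(df$indication_id)) {
    stop_invariant("case-mix indication_ids must be unique")
  }
  structure(df, class = c("case_mix", "data.frame"))
}

#' Annual patient time per stage for one regimen
#'
#' Sums stage times over every cycle of a year of treatment on one route.
#' On the SC pathway, a regimen flagged `first_cycle_always_iv` has exactly
#' its first cycle (the loading cycle if present, otherwise the first combo
#' cycle) administered with the IV profile of that phase; all remaining
#' cycles use SC profiles. A trastuzumab-style loading cycle uses the
#' `loading_combo` profile of the requested route.
#'
#' @param schedule One row of a [regimen_schedules()] table (or the table
#'   subset to one indication).
#' @param profiles A [cycle_profiles()] table covering the phases referenced.
#' @param drug `"rituximab"` or `"trastuzumab"`.
#' @param route `"IV"` or `"SC"`.
#' @return Named numeric vector of annual minutes per stage
#'   (`waiting_min`, `chair_min`, `consultation_min`).
#' @examples
#' prof <- reference_cycle_times()
#' sched <- reference_schedules("trastuzumab")
#' annual_patient_time(sched, prof, "trastuzumab", "IV")
#' @export
annual_patient_time <- function(schedule, profiles, drug, route) {
  drug <- match.arg(drug, DRUGS)
  route <- match.arg(route, ROUTES)
  if (is.data.frame(schedule)) {
    if (nrow(schedule) != 1L) stop_invariant("schedule must be a single row")
    schedule <- as.list(schedule)
  }
  n_load <- schedule$n_loading_cycles
  n_combo <- schedule$n_combo_cycles
  n_maint <- schedule$n_maintenance_cycles

  total <- stats::setNames(numeric(3L), STAGES)
  if (n_load + n_combo + n_maint == 0) return(total)

  # Phase of each cycle of the year, in administration order.
  phases <- c(rep("loading_combo", n_load), rep("combo", n_combo),
              rep("maintenance", n_maint))
  routes <- rep(route, length(phases))
  if (route == "SC" && isTRUE(schedule$first_cycle_always_iv)) {
    routes[1L] <- "IV"
  }
  for (ph in unique(phases)) {
    for (rt in unique(routes[phases == ph])) {
      n <- sum(phases == ph & routes == rt)
      total <- total + n * lookup_profile(profiles, drug, rt, ph)
    }
  }
  total
}

#' Case-mix-weighted monthly patient time
#'
#' The average monthly time a patient of the given drug spends in hospital on
#' one route: per indication, annual stage minutes are divided by 12; the
#' case-mix-weighted mean is taken per stage; each stage is rounded half to
#' even; the monthly total is the sum of the rounded stages (not the rounded
#' sum). See the methods vignette for why that rounding convention is used.
#'
#' @param mix A [case_mix()] table.
#' @param schedules A [regimen_schedules()] table covering every indication
#'   in the mix.
#' @param profiles A [cycle_profiles()] table.
#' @param drug,route Drug and administration route.
#' @return An object of class `monthly_patient_time`: a list with `drug`,
#'   `route`, `stage_monthly_unrounded`, `stage_monthly_rounded`,
#'   `total_unrounded`, `total_rounded`.
#' @examples
#' prof <- reference_cycle_times()
#' weighted_monthly_time(reference_case_mix("rituximab"),
#'                       reference_schedules("rituximab"),
#'                       prof, "rituximab", "IV")
#' @export
weighted_monthly_time <- function(mix, schedules, profiles, drug, route) {
  mix <- case_mix(mix)
  if (!all(mix$indication_id %in% schedules$indication_id)) {
    stop_config("case mix references indications without a schedule: ",
                paste(setdiff(mix$indication_id, schedules$indication_id),
                      collapse = ", "))
  }
  unrounded <- stats::setNames(numeric(3L), STAGES)
  for (k in seq_len(nrow(mix))) {
    sched <- schedules[schedules$indication_id == mix$indication_id[k], ]
    ann <- annual_patient_time(sched, profiles, drug, route)
    unrounded <- unrounded + mix$share[k] * ann / 12
  }
  rounded <- round(unrounded)  # IEC 60559: round half to even
  structure(
    list(drug = drug, route = route,
         stage_monthly_unrounded = unrounded,
         stage_monthly_rounded = rounded,
         total_unrounded = sum(unrounded),
         total_rounded = sum(rounded)),
    class = "monthly_patient_time")
}

#' @export
print.monthly_patient_time <- function(x, ...) {
  cat(sprintf("Monthly patient time: %s, %s route\n", x$drug, x$route))
  tab <- rbind(unrounded = x$stage_monthly_unrounded,
               rounded = x$stage_monthly_rounded)
  print(cbind(tab, total = c(x$total_unrounded, x$total_rounded)))
  invisible(x)
}

#' Monthly hospital-time reduction, IV versus SC
#'
#' The headline quality measure: the percentage by which the monthly time in
#' hospital falls when a patient switches from the IV to the SC pathway,
#' computed from the rounded monthly totals and reported to two decimals,
#' together with its decomposition into waiting-room, chair and consultation
#' deltas.
#'
#' @param iv,sc `monthly_patient_time` objects for the same drug.
#' @return List with `total_pct` (percent, 2 decimals), `stage_delta_min`
#'   (rounded IV minus SC minutes per stage) and `stage_pct` (per-stage
#'   percentage reductions relative to the IV stage values).
#' @examples
#' prof <- reference_cycle_times()
#' iv <- weighted_monthly_time(reference_case_mix("rituximab"),
#'                             reference_schedules("rituximab"),
#'                             prof, "rituximab", "IV")
#' sc <- weighted_monthly_time(reference_case_mix("rituximab"),
#'                             reference_schedules("rituximab"),
#'                             prof, "rituximab", "SC")
#' monthly_time_reduction(iv, sc)$total_pct
#' @export
monthly_time_reduction <- function(iv, sc) {
  if (!inherits(iv, "monthly_patient_time") ||
      !inherits(sc, "monthly_patient_time")) {
    stop_invariant("inputs must be monthly_patient_time objects")
  }
  if (iv$drug != sc$drug) {
    stop_invariant("IV and SC monthly times must be for the same drug")
  }
  if (iv$total_rounded <= 0) {
    stop_invariant("IV monthly total is zero; reduction undefined")
  }
  delta <- iv$stage_monthly_rounded - sc$stage_monthly_rounded
  stage_pct <- ifelse(iv$stage_monthly_rounded > 0,
                      100 * delta / iv$stage_monthly_rounded, NA_real_)
  list(
    total_pct = round(100 * (iv$total_rounded - sc$total_rounded) /
                        iv$total_rounded, 2),
    stage_delta_min = delta,
    stage_pct = stage_pct
  )
}
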