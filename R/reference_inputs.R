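# Built-in reference inputs: the published per-cycle stage times, yearly
# regimen schedules and case mix observed across Spanish reference hospitals
# for rituximab and trastuzumab. These are the model's default generative
# centers and the fixture against which the monthly-time reproduction tests
# run.

#' Reference per-cycle stage times
#'
#' Published average per-visit minutes (waiting room, administration chair,
#' medical consultation) for each drug, route and phase, as reported by
#' Spanish reference hospitals. Trastuzumab has a distinct first cycle
#' (`loading_combo`): the IV form carries a loading dose, and although the SC
#' form needs none, the observed first SC visit is longer than later ones and
#' is kept as its own profile.
#'
#' @return A [cycle_profiles()] table with 10 rows.
#' @export
reference_cycle_times <- function() {
  cycle_profiles(data.frame(
    drug = c(rep("rituximab", 4L), rep("trastuzumab", 6L)),
    route = c("IV", "SC", "IV", "SC",
              "IV", "SC", "IV", "SC", "IV", "SC"),
    phase = c("combo", "combo", "maintenance", "maintenance",
              "loading_combo", "loading_combo", "combo", "combo",
              "maintenance", "maintenance"),
    waiting_min      = c(71, 71, 68, 53, 83, 83, 85, 85, 85, 60),
    chair_min        = c(296, 139, 183, 21, 187, 83, 162, 107, 64, 15),
    consultation_min = c(20, 20, 16, 15, 17, 16, 17, 16, 17, 16)
  ))
}

#' Reference yearly regimen schedules
#'
#' Cycles per year per indication. Rituximab: first-line follicular lymphoma
#' (8 combination cycles + 12 maintenance), relapsed/refractory follicular
#' lymphoma (8 + 8) and diffuse large B-cell lymphoma (8 + 0); the first
#' rituximab cycle is always administered IV. Trastuzumab: 1 loading cycle in
#' combination with chemotherapy + 7 further combination cycles + 10
#' maintenance cycles, 18 cycles/year.
#'
#' @param drug `"rituximab"` or `"trastuzumab"`.
#' @return A [regimen_schedules()] table.
#' @export
reference_schedules <- function(drug = c("rituximab", "trastuzumab")) {
  drug <- match.arg(drug)
  if (drug == "rituximab") {
    regimen_schedules(data.frame(
      indication_id = c("fl_first_line", "fl_relapsed", "dlbcl"),
      n_loading_cycles = c(0L, 0L, 0L),
      n_combo_cycles = c(8L, 8L, 8L),
      n_maintenance_cycles = c(12L, 8L, 0L),
      first_cycle_always_iv = c(TRUE, TRUE, TRUE)
    ))
  } else {
    regimen_schedules(data.frame(
      indication_id = "breast_cancer",
      n_loading_cycles = 1L,
      n_combo_cycles = 7L,
      n_maintenance_cycles = 10L,
      first_cycle_always_iv = FALSE
    ))
  }
}

#' Reference case mix
#'
#' Population shares across indications: 48% first-line follicular lymphoma,
#' 14% relapsed/refractory follicular lymphoma, 38% diffuse large B-cell
#' lymphoma for rituximab; trastuzumab patients are a single breast-cancer
#' population.
#'
#' @inheritParams reference_schedules
#' @return A [case_mix()] table.
#' @export
reference_case_mix <- function(drug = c("rituximab", "trastuzumab")) {
  drug <- match.arg(drug)
  if (drug == "rituximab") {
    case_mix(data.frame(
      indication_id = c("fl_first_line", "fl_relapsed", "dlbcl"),
      share = c(0.48, 0.14, 0.38)
    ))
  } else {
    case_mix(data.frame(indication_id = "breast_cancer", share = 1))
  }
}

#' Monthly patient-time table for the reference inputs
#'
#' Convenience wrapper: computes the case-mix-weighted monthly patient time
#' for every drug and route from the packaged reference inputs, in one table.
#'
#' @param profiles Optional [cycle_profiles()] table; defaults to
#'   [reference_cycle_times()].
#' @return Data frame with one row per drug and route: the three rounded
#'   monthly stage values, the rounded monthly total, and the unrounded total.
#' @export
reference_monthly_times <- function(profiles = reference_cycle_times()) {
  rows <- lapply(DRUGS, function(d) {
    lapply(ROUTES, function(r) {
      m <- weighted_monthly_time(reference_case_mix(d),
                                 reference_schedules(d), profiles, d, r)
      data.frame(drug = d, route = r,
                 waiting_min = m$stage_monthly_rounded[["waiting_min"]],
                 chair_min = m$stage_monthly_rounded[["chair_min"]],
                 consultation_min = m$stage_monthly_rounded[["consultation_min"]],
                 total_min = m$total_rounded,
                 total_unrounded = m$total_unrounded)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}
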