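# Capacity parameters: minutes of chair or laminar-flow-hood time freed by
# SC conversion, converted into additional treatments via the unit's average
# treatment time and into a percentage of current volume. Administration
# parameters use a monthly period; preparation parameters a weekly period.

#' Day-unit and pharmacy resources
#'
#' Resource profile of one hospital's cancer treatment unit (administration
#' chairs) and pharmacy (vertical laminar flow hoods), with current
#' throughput volumes.
#'
#' @param admin_opening_min_per_day Opening minutes per day of the treatment
#'   unit.
#' @param admin_days_per_month Administration days per month.
#' @param n_chairs Number of administration chairs ("positions").
#' @param admin_treatments_per_day Treatments of any drug administered per
#'   day.
#' @param hood_opening_min_per_day Pharmacy hood operating minutes per day.
#' @param hood_days_per_week Hood operating days per week.
#' @param n_hoods Number of vertical laminar flow hoods.
#' @param preparations_per_week Treatment preparations of any drug per week.
#' @return A validated list of class `unit_resources`.
#' @export
unit_resources <- function(admin_opening_min_per_day, admin_days_per_month,
                           n_chairs, admin_treatments_per_day,
                           hood_opening_min_per_day, hood_days_per_week,
                           n_hoods, preparations_per_week) {
  res <- list(admin_opening_min_per_day = admin_opening_min_per_day,
              admin_days_per_month = admin_days_per_month,
              n_chairs = n_chairs,
              admin_treatments_per_day = admin_treatments_per_day,
              hood_opening_min_per_day = hood_opening_min_per_day,
              hood_days_per_week = hood_days_per_week,
              n_hoods = n_hoods,
              preparations_per_week = preparations_per_week)
  num <- vapply(res, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v), logical(1L))
  if (!all(num)) {
    stop_invariant("unit resources must be finite scalars: ",
                   paste(names(res)[!num], collapse = ", "))
  }
  pos <- c("admin_opening_min_per_day", "hood_opening_min_per_day")
  if (any(unlist(res[pos]) <= 0)) stop_invariant("opening minutes must be > 0")
  ge1 <- c("admin_days_per_month", "n_chairs", "admin_treatments_per_day",
           "hood_days_per_week", "n_hoods", "preparations_per_week")
  if (any(unlist(res[ge1]) < 1)) {
    stop_invariant("counts used as divisors must be >= 1")
  }
  structure(res, class = "unit_resources")
}

#' Average administration time of any treatment
#'
#' The mean chair occupancy per treatment implied by the unit's capacity and
#' throughput: total open chair-minutes per day divided by the daily
#' treatment volume.
#'
#' @param resources A [unit_resources()] object.
#' @return Minutes per treatment.
#' @examples
#' res <- unit_resources(600, 21, 10, 60, 480, 5, 2, 240)
#' avg_administration_time(res)  # 600 * 10 / 60 = 100
#' @export
avg_administration_time <- function(resources) {
  stopifnot(inherits(resources, "unit_resources"))
  resources$admin_opening_min_per_day * resources$n_chairs /
    resources$admin_treatments_per_day
}

#' Average preparation time of any treatment
#'
#' Mean hood time per preparation on a weekly basis: weekly hood operating
#' minutes times the number of hoods, divided by weekly preparation volume.
#'
#' @inheritParams avg_administration_time
#' @return Minutes per preparation.
#' @examples
#' res <- unit_resources(600, 21, 10, 60, 480, 5, 2, 240)
#' avg_preparation_time(res)  # 480 * 5 * 2 / 240 = 20
#' @export
avg_preparation_time <- function(resources) {
  stopifnot(inherits(resources, "unit_resources"))
  resources$hood_opening_min_per_day * resources$hood_days_per_week *
    resources$n_hoods / resources$preparations_per_week
}

#' Conversion activity of one hospital
#'
#' The factors entering the four capacity parameters: how many patients are
#' converted to SC per drug and phase, their visit frequencies, the
#' chair-time difference per visit, plus premedication, regional-referral and
#' pharmacy-preparation quantities. Negative time deltas (SC slower than IV)
#' are allowed but flagged with a warning.
#'
#' @param conversions Data frame with columns `drug`, `phase`,
#'   `n_converted`, `visits_per_month`, `delta_chair_min_per_visit`
#'   (IV chair minutes minus SC chair minutes).
#' @param premed_chair_min Chair minutes per visit freed when rituximab
#'   premedication moves to the waiting room.
#' @param n_premed_patients,premed_visits_per_month Patients and monthly
#'   visits affected by waiting-room premedication.
#' @param n_referred_patients,referred_visits_per_month Patients referred to
#'   a regional hospital for SC administration and their monthly visits.
#' @param referred_delta_chair_min IV-vs-SC chair-time difference per visit
#'   applied to referred patients.
#' @param doses_prepared_regionally_per_week Doses whose preparation moves to
#'   the regional hospital.
#' @param delta_prep_min_per_dose IV hood preparation minutes minus SC
#'   preparation minutes, per dose.
#' @param sc_doses_prepared_per_week SC doses prepared per week.
#' @param sc_prep_min_per_dose SC preparation minutes per dose.
#' @param prep_relocated_to_unit Logical: is SC preparation performed outside
#'   the hood (at the treatment unit)?
#' @return A validated list of class `conversion_activity`.
#' @export
conversion_activity <- function(conversions = data.frame(
                                  drug = character(), phase = character(),
                                  n_converted = numeric(),
                                  visits_per_month = numeric(),
                                  delta_chair_min_per_visit = numeric()),
                                premed_chair_min = 0,
                                n_premed_patients = 0,
                                premed_visits_per_month = 0,
                                n_referred_patients = 0,
                                referred_visits_per_month = 0,
                                referred_delta_chair_min = 0,
                                doses_prepared_regionally_per_week = 0,
                                delta_prep_min_per_dose = 0,
                                sc_doses_prepared_per_week = 0,
                                sc_prep_min_per_dose = 0,
                                prep_relocated_to_unit = FALSE) {
  needed <- c("drug", "phase", "n_converted", "visits_per_month",
              "delta_chair_min_per_visit")
  if (!all(needed %in% names(conversions))) {
    stop_invariant("conversions table lacks columns: ",
                   paste(setdiff(needed, names(conversions)), collapse = ", "))
  }
  counts <- c(conversions$n_converted, conversions$visits_per_month,
              n_premed_patients, premed_visits_per_month, n_referred_patients,
              referred_visits_per_month, doses_prepared_regionally_per_week,
              sc_doses_prepared_per_week)
  if (any(counts < 0)) stop_invariant("activity counts must be >= 0")
  deltas <- c(conversions$delta_chair_min_per_visit, referred_delta_chair_min,
              delta_prep_min_per_dose)
  if (any(deltas < 0)) {
    warning("negative time delta: SC slower than IV for some activity; ",
            "capacity impacts will be negative", call. = FALSE)
  }
  structure(list(conversions = as.data.frame(conversions)[needed],
                 premed_chair_min = premed_chair_min,
                 n_premed_patients = n_premed_patients,
                 premed_visits_per_month = premed_visits_per_month,
                 n_referred_patients = n_referred_patients,
                 referred_visits_per_month = referred_visits_per_month,
                 referred_delta_chair_min = referred_delta_chair_min,
                 doses_prepared_regionally_per_week =
                   doses_prepared_regionally_per_week,
                 delta_prep_min_per_dose = delta_prep_min_per_dose,
                 sc_doses_prepared_per_week = sc_doses_prepared_per_week,
                 sc_prep_min_per_dose = sc_prep_min_per_dose,
                 prep_relocated_to_unit = isTRUE(prep_relocated_to_unit)),
            class = "conversion_activity")
}

# One computed capacity parameter. additional_treatments =
# minutes_saved / avg_unit_time; pct_increase = 100 * additional / volume.
capacity_impact <- function(parameter_id, minutes_saved, avg_unit_time,
                            current_volume, period) {
  if (avg_unit_time <= 0) stop_invariant("average unit time must be > 0")
  if (current_volume <= 0) stop_invariant("current period volume must be > 0")
  additional <- minutes_saved / avg_unit_time
  structure(list(parameter_id = parameter_id,
                 minutes_saved_per_period = minutes_saved,
                 avg_unit_time_min = avg_unit_time,
                 additional_treatments = additional,
                 pct_increase = 100 * additional / current_volume,
                 period = period),
            class = "capacity_impact")
}

#' @export
print.capacity_impact <- function(x, ...) {
  cat(sprintf("%s: %.1f min/%s saved -> %.2f extra treatments (+%.2f%%)\n",
              x$parameter_id, x$minutes_saved_per_period, x$period,
              x$additional_treatments, x$pct_increase))
  invisible(x)
}

monthly_admin_volume <- function(resources) {
  resources$admin_treatments_per_day * resources$admin_days_per_month
}

#' Capacity gain from IV-to-SC conversion (parameter 1)
#'
#' Chair minutes freed per month by administering converted patients SC
#' instead of IV, summed over drug and phase:
#' delta chair minutes x converted patients x monthly visits; converted into
#' additional monthly treatments via [avg_administration_time()].
#'
#' @param activity A [conversion_activity()] object.
#' @param resources A [unit_resources()] object.
#' @param current_monthly_volume Current treatments per month; defaults to
#'   daily volume times administration days.
#' @return A `capacity_impact` (parameter id `P1`, monthly period).
#' @export
p1_conversion_gain <- function(activity, resources,
                               current_monthly_volume =
                                 monthly_admin_volume(resources)) {
  stopifnot(inherits(activity, "conversion_activity"))
  cv <- activity$conversions
  mins <- sum(cv$delta_chair_min_per_visit * cv$n_converted *
                cv$visits_per_month)
  capacity_impact("P1", mins, avg_administration_time(resources),
                  current_monthly_volume, "month")
}

#' Capacity gain from waiting-room premedication (parameter 2)
#'
#' Chair minutes freed per month when rituximab premedication is given in the
#' waiting room rather than in the administration chair.
#'
#' @inheritParams p1_conversion_gain
#' @return A `capacity_impact` (parameter id `P2`, monthly period).
#' @export
p2_premed_gain <- function(activity, resources,
                           current_monthly_volume =
                             monthly_admin_volume(resources)) {
  stopifnot(inherits(activity, "conversion_activity"))
  mins <- activity$premed_chair_min * activity$n_premed_patients *
    activity$premed_visits_per_month
  capacity_impact("P2", mins, avg_administration_time(resources),
                  current_monthly_volume, "month")
}

#' Capacity gain from regional referral (parameter 3)
#'
#' Patients receiving SC treatment at a regional hospital closer to home free
#' capacity at the reference hospital on both sides: administration (IV-vs-SC
#' chair-time difference x referred patients x visits, monthly) and pharmacy
#' preparation (IV-vs-SC preparation-time difference x doses prepared
#' regionally, weekly).
#'
#' @inheritParams p1_conversion_gain
#' @param current_weekly_preparations Current hood preparations per week.
#' @return List with elements `admin` (`P3_admin`, monthly) and `prep`
#'   (`P3_prep`, weekly).
#' @export
p3_referral_gain <- function(activity, resources,
                             current_monthly_volume =
                               monthly_admin_volume(resources),
                             current_weekly_preparations =
                               resources$preparations_per_week) {
  stopifnot(inherits(activity, "conversion_activity"))
  admin_min <- activity$referred_delta_chair_min *
    activity$n_referred_patients * activity$referred_visits_per_month
  prep_min <- activity$delta_prep_min_per_dose *
    activity$doses_prepared_regionally_per_week
  list(admin = capacity_impact("P3_admin", admin_min,
                               avg_administration_time(resources),
                               current_monthly_volume, "month"),
       prep = capacity_impact("P3_prep", prep_min,
                              avg_preparation_time(resources),
                              current_weekly_preparations, "week"))
}

#' Pharmacy-hood capacity gain (parameter 4)
#'
#' Weekly hood minutes freed (a) because SC doses take less preparation time
#' than IV doses (preparation-time difference x SC doses per week) and (b)
#' additionally, when SC preparation is relocated to the treatment unit, the
#' entire SC preparation time leaves the hood.
#'
#' @inheritParams p3_referral_gain
#' @return List with elements `p4a` (conversion effect) and `p4b`
#'   (relocation effect; zero when `prep_relocated_to_unit` is off), both
#'   weekly `capacity_impact`s.
#' @export
p4_preparation_gain <- function(activity, resources,
                                current_weekly_preparations =
                                  resources$preparations_per_week) {
  stopifnot(inherits(activity, "conversion_activity"))
  a_min <- activity$delta_prep_min_per_dose *
    activity$sc_doses_prepared_per_week
  b_min <- if (activity$prep_relocated_to_unit) {
    activity$sc_prep_min_per_dose * activity$sc_doses_prepared_per_week
  } else 0
  avg <- avg_preparation_time(resources)
  list(p4a = capacity_impact("P4a", a_min, avg, current_weekly_preparations,
                             "week"),
       p4b = capacity_impact("P4b", b_min, avg, current_weekly_preparations,
                             "week"))
}
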