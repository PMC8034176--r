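# Quality parameters: valuation of hospital time saved as caregiver/patient
# labor productivity, and reduction in venous-access-device use.

#' Labor-cost model
#'
#' Converts time in hospital into a productivity value. When salary and
#' working hours are supplied, the cost per minute is derived as
#' salary / (12 x hours x 60). When called with no arguments it uses the
#' Spanish labor-market constant of 0.205464 EUR/min (average annual gross
#' salary EUR 23,022.20 at 155.6 working hours per month; the published
#' constant reflects a slightly more precise hours figure than the printed
#' one, so deriving from the printed inputs gives 0.20550).
#'
#' @param annual_gross_salary_eur Average annual gross salary, EUR/year.
#' @param working_hours_per_month Working hours per month.
#' @param cost_per_minute_eur Optional explicit EUR/min; overrides the
#'   derivation.
#' @return A list of class `labor_cost_model` with the three fields.
#' @examples
#' cost_per_minute(labor_cost_model())                # published constant
#' cost_per_minute(labor_cost_model(23022.20, 155.6)) # derived
#' @export
labor_cost_model <- function(annual_gross_salary_eur = NULL,
                             working_hours_per_month = NULL,
                             cost_per_minute_eur = NULL) {
  if (is.null(cost_per_minute_eur)) {
    if (is.null(annual_gross_salary_eur) || is.null(working_hours_per_month)) {
      # default: published constant
      cost_per_minute_eur <- 0.205464
    } else {
      if (annual_gross_salary_eur < 0) stop_invariant("salary must be >= 0")
      if (working_hours_per_month <= 0) {
        stop_invariant("working hours per month must be > 0")
      }
      cost_per_minute_eur <- annual_gross_salary_eur /
        (12 * working_hours_per_month * 60)
    }
  }
  structure(list(annual_gross_salary_eur = annual_gross_salary_eur,
                 working_hours_per_month = working_hours_per_month,
                 cost_per_minute_eur = cost_per_minute_eur),
            class = "labor_cost_model")
}

#' Professional cost per minute
#'
#' @param model A [labor_cost_model()].
#' @return EUR per minute.
#' @export
cost_per_minute <- function(model) {
  stopifnot(inherits(model, "labor_cost_model"))
  model$cost_per_minute_eur
}

#' Labor-productivity gain from time saved
#'
#' Values the monthly reduction in time spent in hospital at the professional
#' cost per minute. A percentage gain is reported only when an explicit
#' baseline (productive minutes per month) is supplied; no published
#' denominator exists, so none is assumed.
#'
#' @param minutes_saved_per_patient_month Minutes of hospital time saved per
#'   patient per month.
#' @param cost_model A [labor_cost_model()].
#' @param baseline_minutes_per_month Optional denominator for `pct_gain`.
#' @return List of class `productivity_impact`: `minutes_saved_per_patient_month`,
#'   `eur_saved_per_patient_month`, and `pct_gain` (NA when no baseline).
#' @examples
#' productivity_gain(193, labor_cost_model())  # EUR 39.65/patient/month
#' @export
productivity_gain <- function(minutes_saved_per_patient_month, cost_model,
                              baseline_minutes_per_month = NULL) {
  if (!is.finite(minutes_saved_per_patient_month)) {
    stop_invariant("minutes saved must be finite")
  }
  eur <- minutes_saved_per_patient_month * cost_per_minute(cost_model)
  pct <- if (is.null(baseline_minutes_per_month)) NA_real_ else {
    if (baseline_minutes_per_month <= 0) {
      stop_invariant("baseline minutes must be > 0")
    }
    100 * minutes_saved_per_patient_month / baseline_minutes_per_month
  }
  structure(list(minutes_saved_per_patient_month =
                   minutes_saved_per_patient_month,
                 eur_saved_per_patient_month = eur,
                 pct_gain = pct),
            class = "productivity_impact")
}

#' Venous-access-device reduction
#'
#' SC trastuzumab lets early breast-cancer patients use a peripherally
#' inserted central catheter (PICC, removed at maintenance) instead of an
#' implanted port-a-cath. Reports the percentage reduction in device use rate
#' and, when device-time data are given, in device time.
#'
#' @param n_port_a_cath_iv Patients requiring a port-a-cath during IV
#'   maintenance treatment (baseline; must be > 0).
#' @param n_picc_sc Patients carrying a PICC during SC maintenance treatment.
#' @param device_time_iv,device_time_sc Optional total device-days under each
#'   route.
#' @return List of class `venous_access_impact` with the counts, times and
#'   `rate_reduction_pct` / `time_reduction_pct` (NA when times absent).
#' @examples
#' device_reduction(100, 19)$rate_reduction_pct  # 81
#' @export
device_reduction <- function(n_port_a_cath_iv, n_picc_sc,
                             device_time_iv = NULL, device_time_sc = NULL) {
  if (any(c(n_port_a_cath_iv, n_picc_sc) < 0)) {
    stop_invariant("device counts must be >= 0")
  }
  if (n_port_a_cath_iv == 0) {
    stop_invariant("no baseline port-a-cath use; rate reduction undefined")
  }
  rate <- 100 * (n_port_a_cath_iv - n_picc_sc) / n_port_a_cath_iv
  time_pct <- NA_real_
  if (!is.null(device_time_iv) && !is.null(device_time_sc)) {
    if (any(c(device_time_iv, device_time_sc) < 0)) {
      stop_invariant("device times must be >= 0")
    }
    if (device_time_iv == 0) {
      stop_invariant("no baseline device time; time reduction undefined")
    }
    time_pct <- 100 * (device_time_iv - device_time_sc) / device_time_iv
  }
  structure(list(n_port_a_cath_iv = n_port_a_cath_iv, n_picc_sc = n_picc_sc,
                 rate_reduction_pct = rate,
                 device_time_iv = device_time_iv,
                 device_time_sc = device_time_sc,
                 time_reduction_pct = time_pct),
            class = "venous_access_impact")
}
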