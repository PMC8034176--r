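# Scenario engine: translates a hospital's observed practice plus a
# conversion scenario (current vs maximal SC use with all efficiency
# processes enabled) into the capacity and quality parameters, and
# aggregates results across hospitals as the mean percentage variation.

#' Efficiency process flags
#'
#' The five processes hospitals implement to exploit SC administration:
#' a dedicated SC administration chair with separate protocols, rituximab
#' premedication given in the waiting room, referral of SC patients to their
#' regional hospital, preparation of SC doses outside the laminar flow hood,
#' and avoidance of venous access devices with reservoirs.
#'
#' @param dedicated_sc_chair,premed_in_waiting_room,regional_referral,prep_outside_hood,avoid_venous_device
#'   Independent logical flags.
#' @return A logical vector of class `process_flags`.
#' @export
process_flags <- function(dedicated_sc_chair = FALSE,
                          premed_in_waiting_room = FALSE,
                          regional_referral = FALSE,
                          prep_outside_hood = FALSE,
                          avoid_venous_device = FALSE) {
  x <- c(dedicated_sc_chair = dedicated_sc_chair,
         premed_in_waiting_room = premed_in_waiting_room,
         regional_referral = regional_referral,
         prep_outside_hood = prep_outside_hood,
         avoid_venous_device = avoid_venous_device)
  if (!is.logical(x) || anyNA(x)) stop_invariant("flags must be TRUE/FALSE")
  structure(x, class = "process_flags")
}

# SmPC caps: share of all doses eligible for the SC formulation.
SMPC_CAPS <- c(rituximab = 0.45, trastuzumab = 0.91)

#' Conversion scenario
#'
#' A per-drug target share of doses administered SC, the process flags in
#' force, and the SmPC eligibility caps (45% of rituximab doses, 91% of
#' trastuzumab doses). Fractions may not exceed their caps.
#'
#' @param sc_dose_fraction Named numeric vector (names in
#'   `c("rituximab", "trastuzumab")`): target SC share of all doses.
#' @param flags A [process_flags()] object.
#' @param caps Named per-drug maximum fractions; defaults to the SmPC caps.
#' @return A list of class `conversion_scenario`.
#' @export
conversion_scenario <- function(sc_dose_fraction, flags = process_flags(),
                                caps = SMPC_CAPS[names(sc_dose_fraction)]) {
  if (is.null(names(sc_dose_fraction)) ||
      !all(names(sc_dose_fraction) %in% DRUGS)) {
    stop_invariant("sc_dose_fraction must be named with known drugs")
  }
  caps <- caps[names(sc_dose_fraction)]
  if (any(caps < 0) || any(caps > 1)) stop_invariant("caps must lie in [0, 1]")
  if (any(sc_dose_fraction < 0) || any(sc_dose_fraction > caps + 1e-12)) {
    stop_invariant("SC dose fractions must satisfy 0 <= fraction <= cap")
  }
  if (!inherits(flags, "process_flags")) flags <- do.call(process_flags, as.list(flags))
  structure(list(sc_dose_fraction = sc_dose_fraction, flags = flags,
                 caps = caps),
            class = "conversion_scenario")
}

#' Maximal SmPC-permitted conversion scenario
#'
#' The hypothetical-hospital scenario: every eligible dose is given SC
#' (fractions at the SmPC caps: 45% rituximab, 91% trastuzumab), all five
#' efficiency processes enabled. The first rituximab dose remains IV in all
#' patients; that rule is enforced by the treatment-time model, not by the
#' fraction.
#'
#' @param drugs Character vector of drugs in the scenario.
#' @return A [conversion_scenario()].
#' @examples
#' max_conversion_scenario("rituximab")$sc_dose_fraction
#' @export
max_conversion_scenario <- function(drugs = c("rituximab", "trastuzumab")) {
  if (!all(drugs %in% DRUGS)) {
    stop_config("unknown drug: ", paste(setdiff(drugs, DRUGS), collapse = ", "))
  }
  conversion_scenario(
    SMPC_CAPS[drugs],
    process_flags(TRUE, TRUE, TRUE, TRUE, TRUE),
    caps = SMPC_CAPS[drugs])
}

#' Hospital profile
#'
#' Everything the model needs about one hospital: its resources, the treated
#' populations per drug and phase with their current SC shares, the
#' quantities feeding the premedication, referral and pharmacy-preparation
#' parameters, which efficiency processes it has implemented, and its
#' venous-access-device counts.
#'
#' @param hospital_id Identifier string.
#' @param drugs Drugs the hospital administers.
#' @param resources A [unit_resources()] object.
#' @param patients Data frame with columns `drug`, `phase` (`combo` or
#'   `maintenance`), `n_patients`, `visits_per_month`, `sc_fraction`
#'   (current share of these patients treated SC).
#' @param premed_chair_min Chair minutes per visit occupied by rituximab
#'   premedication when it is not moved to the waiting room.
#' @param n_referred_patients,referred_visits_per_month Current regional
#'   referral activity (patients and visits per month).
#' @param referred_drug Drug of the referred patients.
#' @param weekly_doses Data frame `drug`, `doses_per_week`: total doses of
#'   each drug prepared per week.
#' @param iv_prep_min_per_dose,sc_prep_min_per_dose Pharmacy preparation
#'   minutes per dose by route.
#' @param regional_dose_share Share of SC doses whose preparation moves to
#'   the regional hospital when referral is active.
#' @param flags A [process_flags()] object (processes currently implemented).
#' @param n_port_a_cath_iv,n_picc_sc,device_time_iv,device_time_sc
#'   Venous-access-device counts and device-days.
#' @param profiles A [cycle_profiles()] table; defaults to
#'   [reference_cycle_times()].
#' @return A list of class `hospital_profile`.
#' @export
hospital_profile <- function(hospital_id, drugs, resources, patients,
                             premed_chair_min = 0,
                             n_referred_patients = 0,
                             referred_visits_per_month = 0,
                             referred_drug = "trastuzumab",
                             weekly_doses = data.frame(
                               drug = drugs, doses_per_week = 0),
                             iv_prep_min_per_dose = 0,
                             sc_prep_min_per_dose = 0,
                             regional_dose_share = 0,
                             flags = process_flags(),
                             n_port_a_cath_iv = 0, n_picc_sc = 0,
                             device_time_iv = 0, device_time_sc = 0,
                             profiles = reference_cycle_times()) {
  if (!all(drugs %in% DRUGS)) stop_invariant("unknown drug in profile")
  need <- c("drug", "phase", "n_patients", "visits_per_month", "sc_fraction")
  if (!all(need %in% names(patients))) {
    stop_invariant("patients table lacks columns: ",
                   paste(setdiff(need, names(patients)), collapse = ", "))
  }
  if (any(patients$sc_fraction < 0) || any(patients$sc_fraction > 1)) {
    stop_invariant("current SC fractions must lie in [0, 1]")
  }
  if (any(patients$n_patients < 0) || any(patients$visits_per_month < 0)) {
    stop_invariant("patient counts and visit rates must be >= 0")
  }
  if (!all(patients$drug %in% drugs)) {
    stop_invariant("patients table lists a drug the hospital does not treat")
  }
  structure(list(hospital_id = hospital_id, drugs = drugs,
                 resources = resources,
                 patients = as.data.frame(patients)[need],
                 premed_chair_min = premed_chair_min,
                 n_referred_patients = n_referred_patients,
                 referred_visits_per_month = referred_visits_per_month,
                 referred_drug = referred_drug,
                 weekly_doses = as.data.frame(weekly_doses),
                 iv_prep_min_per_dose = iv_prep_min_per_dose,
                 sc_prep_min_per_dose = sc_prep_min_per_dose,
                 regional_dose_share = regional_dose_share,
                 flags = flags,
                 n_port_a_cath_iv = n_port_a_cath_iv, n_picc_sc = n_picc_sc,
                 device_time_iv = device_time_iv,
                 device_time_sc = device_time_sc,
                 profiles = profiles),
            class = "hospital_profile")
}

# Current overall SC dose share of one drug (patient-visit weighted).
current_sc_fraction <- function(hospital, drug) {
  p <- hospital$patients[hospital$patients$drug == drug, ]
  w <- p$n_patients * p$visits_per_month
  if (sum(w) == 0) return(0)
  sum(w * p$sc_fraction) / sum(w)
}

# Per-visit chair-time difference (IV minus SC) for a drug and phase.
chair_delta <- function(profiles, drug, phase) {
  lookup_profile(profiles, drug, "IV", phase)[["chair_min"]] -
    lookup_profile(profiles, drug, "SC", phase)[["chair_min"]]
}

#' Translate a scenario into a hospital's conversion activity
#'
#' Converted patient counts scale proportionally with the scenario's SC dose
#' fraction relative to the hospital's current fraction, capped at the
#' treated population (and, for a hospital with no current SC use, the
#' scenario fraction is applied to each phase directly). Scenarios only move
#' toward more SC: a fraction below the current observed share is an error.
#' The process flags of the scenario gate premedication (P2), referral (P3)
#' and preparation relocation (P4b).
#'
#' @param hospital A [hospital_profile()].
#' @param scenario A [conversion_scenario()]; fractions for drugs the
#'   hospital does not treat are ignored.
#' @return A [conversion_activity()] object.
#' @export
apply_scenario <- function(hospital, scenario) {
  stopifnot(inherits(hospital, "hospital_profile"),
            inherits(scenario, "conversion_scenario"))
  pats <- hospital$patients
  pats$target_fraction <- pats$sc_fraction
  for (d in intersect(hospital$drugs, names(scenario$sc_dose_fraction))) {
    f_cur <- current_sc_fraction(hospital, d)
    f_new <- scenario$sc_dose_fraction[[d]]
    if (f_new < f_cur - 1e-9) {
      # A hospital can already exceed the SmPC cap (caps count all label
      # doses; observed shares count administered doses), so an at-cap
      # scenario is a no-op there. Any other shortfall is a user error.
      if (f_new >= scenario$caps[[d]] - 1e-9) {
        f_new <- f_cur
      } else {
        stop_config("scenario SC fraction for ", d, " (", f_new,
                    ") is below the hospital's current share (",
                    round(f_cur, 4), "); scenarios only increase SC use")
      }
    }
    idx <- pats$drug == d
    pats$target_fraction[idx] <- if (f_cur > 0) {
      pmin(1, pats$sc_fraction[idx] * f_new / f_cur)
    } else f_new
  }
  conv <- data.frame(
    drug = pats$drug, phase = pats$phase,
    n_converted = pats$n_patients * pats$target_fraction,
    visits_per_month = pats$visits_per_month,
    delta_chair_min_per_visit = mapply(chair_delta, pats$drug, pats$phase,
                                       MoreArgs = list(profiles = hospital$profiles)))

  flags <- scenario$flags
  # P2: premedication moves to the waiting room for SC rituximab
  # maintenance patients.
  rm_idx <- pats$drug == "rituximab" & pats$phase == "maintenance"
  n_premed <- if (flags[["premed_in_waiting_room"]] && any(rm_idx)) {
    sum(pats$n_patients[rm_idx] * pats$target_fraction[rm_idx])
  } else 0
  premed_visits <- if (n_premed > 0) {
    stats::weighted.mean(pats$visits_per_month[rm_idx],
                         pats$n_patients[rm_idx] * pats$target_fraction[rm_idx])
  } else 0

  # P3: referral activity scales with the referred drug's fraction.
  ref_scale <- 0
  if (flags[["regional_referral"]] && hospital$n_referred_patients > 0) {
    d <- hospital$referred_drug
    f_cur <- current_sc_fraction(hospital, d)
    f_new <- if (d %in% names(scenario$sc_dose_fraction)) {
      max(scenario$sc_dose_fraction[[d]], f_cur)
    } else f_cur
    ref_scale <- if (f_cur > 0) f_new / f_cur else 1
  }
  ref_delta <- if (ref_scale > 0) {
    chair_delta(hospital$profiles, hospital$referred_drug, "maintenance")
  } else 0

  # P4: SC doses prepared per week under the scenario.
  wd <- hospital$weekly_doses
  sc_doses <- 0
  for (k in seq_len(nrow(wd))) {
    d <- wd$drug[k]
    f <- if (d %in% names(scenario$sc_dose_fraction)) {
      scenario$sc_dose_fraction[[d]]
    } else current_sc_fraction(hospital, d)
    sc_doses <- sc_doses + wd$doses_per_week[k] * f
  }
  regional_doses <- if (flags[["regional_referral"]]) {
    sc_doses * hospital$regional_dose_share
  } else 0

  conversion_activity(
    conversions = conv,
    premed_chair_min = hospital$premed_chair_min,
    n_premed_patients = n_premed,
    premed_visits_per_month = premed_visits,
    n_referred_patients = hospital$n_referred_patients * ref_scale,
    referred_visits_per_month = hospital$referred_visits_per_month,
    referred_delta_chair_min = ref_delta,
    doses_prepared_regionally_per_week = regional_doses,
    delta_prep_min_per_dose = hospital$iv_prep_min_per_dose -
      hospital$sc_prep_min_per_dose,
    sc_doses_prepared_per_week = sc_doses - regional_doses,
    sc_prep_min_per_dose = hospital$sc_prep_min_per_dose,
    prep_relocated_to_unit = flags[["prep_outside_hood"]])
}

#' Evaluate all seven parameters for one hospital under a scenario
#'
#' Runs the treatment-time, capacity and quality models and assembles one
#' result: the six capacity impacts (and their sum), the per-drug monthly
#' hospital-time reductions weighted by the scenario's SC share, the
#' labor-productivity valuation of those savings, and the venous-access
#' reduction (when the avoidance process is active).
#'
#' @param hospital A [hospital_profile()].
#' @param scenario A [conversion_scenario()].
#' @param cost_model A [labor_cost_model()].
#' @return Object of class `hospital_result`; its `$table` is a data frame
#'   `(hospital_id, parameter, value, units)` with `NA` for parameters the
#'   hospital cannot contribute (e.g. no rituximab service).
#' @export
evaluate_hospital <- function(hospital, scenario,
                              cost_model = labor_cost_model()) {
  act <- apply_scenario(hospital, scenario)
  res <- hospital$resources
  p1 <- p1_conversion_gain(act, res)
  p2 <- p2_premed_gain(act, res)
  p3 <- p3_referral_gain(act, res)
  p4 <- p4_preparation_gain(act, res)
  impacts <- list(P1 = p1, P2 = p2, P3_admin = p3$admin, P3_prep = p3$prep,
                  P4a = p4$p4a, P4b = p4$p4b)

  quality <- list()
  rows <- data.frame(hospital_id = hospital$hospital_id,
                     parameter = names(impacts),
                     value = vapply(impacts, function(x) x$pct_increase,
                                    numeric(1L)),
                     units = "%")
  # Components 1 + 2 + 3 + 4b of the capacity story, as a single headline.
  rows <- rbind(rows, data.frame(
    hospital_id = hospital$hospital_id, parameter = "capacity_pct_sum",
    value = p1$pct_increase + p2$pct_increase + p3$admin$pct_increase +
      p3$prep$pct_increase + p4$p4b$pct_increase,
    units = "%"))

  for (d in DRUGS) {
    if (!d %in% hospital$drugs) {
      rows <- rbind(rows, data.frame(
        hospital_id = hospital$hospital_id,
        parameter = c(paste0("time_reduction_", d),
                      paste0("productivity_eur_", d)),
        value = NA_real_, units = c("%", "EUR/patient/month")))
      next
    }
    iv <- weighted_monthly_time(reference_case_mix(d), reference_schedules(d),
                                hospital$profiles, d, "IV")
    sc <- weighted_monthly_time(reference_case_mix(d), reference_schedules(d),
                                hospital$profiles, d, "SC")
    red <- monthly_time_reduction(iv, sc)
    # effective share never drops below current practice (see apply_scenario)
    f <- if (d %in% names(scenario$sc_dose_fraction)) {
      max(scenario$sc_dose_fraction[[d]],
          min(current_sc_fraction(hospital, d), 1))
    } else current_sc_fraction(hospital, d)
    # Hospital-level monthly time reduction: the per-patient IV-vs-SC
    # reduction realised for the SC-treated share of the population.
    mins_saved <- f * (iv$total_rounded - sc$total_rounded)
    prod <- productivity_gain(mins_saved, cost_model)
    quality[[d]] <- list(per_patient_reduction = red, productivity = prod)
    rows <- rbind(rows, data.frame(
      hospital_id = hospital$hospital_id,
      parameter = c(paste0("time_reduction_", d),
                    paste0("productivity_eur_", d)),
      value = c(round(100 * mins_saved / iv$total_rounded, 2),
                prod$eur_saved_per_patient_month),
      units = c("%", "EUR/patient/month")))
  }

  dev_val <- c(NA_real_, NA_real_)
  if ("trastuzumab" %in% hospital$drugs && hospital$n_port_a_cath_iv > 0) {
    if (scenario$flags[["avoid_venous_device"]]) {
      dev <- device_reduction(hospital$n_port_a_cath_iv, hospital$n_picc_sc,
                              hospital$device_time_iv, hospital$device_time_sc)
      quality$device <- dev
      dev_val <- c(dev$rate_reduction_pct, dev$time_reduction_pct)
    } else {
      dev_val <- c(0, 0)  # no avoidance process: no reduction realised
    }
  }
  rows <- rbind(rows, data.frame(
    hospital_id = hospital$hospital_id,
    parameter = c("device_rate_reduction", "device_time_reduction"),
    value = dev_val, units = "%"))
  rownames(rows) <- NULL

  structure(list(hospital_id = hospital$hospital_id, scenario = scenario,
                 activity = act, impacts = impacts, quality = quality,
                 table = rows),
            class = "hospital_result")
}

#' @export
print.hospital_result <- function(x, ...) {
  cat("Hospital", x$hospital_id, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Aggregate results across hospitals
#'
#' Unweighted arithmetic mean of each parameter's percentage variation over
#' the hospitals that contribute it; hospitals lacking a parameter (value
#' `NA`) are excluded from that parameter's mean.
#'
#' @param results A list of `hospital_result` objects.
#' @return Data frame `(parameter, mean_value, units, n_hospitals)`.
#' @export
aggregate_hospitals <- function(results) {
  if (length(results) == 0L) stop_invariant("no hospital results to aggregate")
  if (!all(vapply(results, inherits, logical(1L), "hospital_result"))) {
    stop_invariant("all elements must be hospital_result objects")
  }
  long <- do.call(rbind, lapply(results, `[[`, "table"))
  out <- do.call(rbind, lapply(split(long, long$parameter), function(g) {
    ok <- !is.na(g$value)
    data.frame(parameter = g$parameter[1L],
               mean_value = if (any(ok)) mean(g$value[ok]) else NA_real_,
               units = g$units[1L],
               n_hospitals = sum(ok))
  }))
  # stable, readable order
  ord <- c("P1", "P2", "P3_admin", "P3_prep", "P4a", "P4b",
           "capacity_pct_sum",
           "time_reduction_rituximab", "time_reduction_trastuzumab",
           "productivity_eur_rituximab", "productivity_eur_trastuzumab",
           "device_rate_reduction", "device_time_reduction")
  out <- out[match(ord[ord %in% out$parameter], out$parameter), ]
  rownames(out) <- NULL
  out
}
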