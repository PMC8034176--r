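# Independent oracles and small builders shared across tests.

# Brute-force monthly time: walk every cycle of every indication one at a
# time, adding the stage times of the profile that cycle uses, then average.
# Deliberately implemented cycle-by-cycle, independent of the vectorised
# path in weighted_monthly_time.
brute_monthly_time <- function(mix, schedules, profiles, drug, route) {
  pdf <- as.data.frame(profiles)
  one <- function(d, r, ph) {
    row <- pdf[pdf$drug == d & pdf$route == r & pdf$phase == ph, ]
    c(row$waiting_min, row$chair_min, row$consultation_min)
  }
  acc <- c(0, 0, 0)
  for (k in seq_len(nrow(mix))) {
    s <- schedules[schedules$indication_id == mix$indication_id[k], ]
    year <- c(0, 0, 0)
    cycle_no <- 0
    for (ph in c(rep("loading_combo", s$n_loading_cycles),
                 rep("combo", s$n_combo_cycles),
                 rep("maintenance", s$n_maintenance_cycles))) {
      cycle_no <- cycle_no + 1
      r <- route
      if (route == "SC" && isTRUE(s$first_cycle_always_iv) && cycle_no == 1) {
        r <- "IV"
      }
      year <- year + one(drug, r, ph)
    }
    acc <- acc + mix$share[k] * year / 12
  }
  acc
}

# Randomly perturbed copy of the reference profile table (non-negative).
perturbed_profiles <- function(scale = 10) {
  df <- as.data.frame(reference_cycle_times())
  for (s in c("waiting_min", "chair_min", "consultation_min")) {
    df[[s]] <- pmax(0, df[[s]] + stats::runif(nrow(df), -scale, scale))
  }
  cycle_profiles(df)
}

# A deterministic, fully specified hospital for scenario hand calculations.
toy_hospital <- function(sc_combo = 0.2, sc_maint = 0.4,
                         flags = process_flags(TRUE, TRUE, TRUE, TRUE, TRUE),
                         hospital_id = "toy") {
  hospital_profile(
    hospital_id = hospital_id,
    drugs = c("rituximab", "trastuzumab"),
    resources = unit_resources(600, 20, 10, 60, 480, 5, 2, 240),
    patients = data.frame(
      drug = rep(c("rituximab", "trastuzumab"), each = 2),
      phase = rep(c("combo", "maintenance"), 2),
      n_patients = c(20, 30, 25, 40),
      visits_per_month = c(1, 1, 1, 1),
      sc_fraction = c(sc_combo, sc_maint, sc_combo, sc_maint)),
    premed_chair_min = 30,
    n_referred_patients = 4,
    referred_visits_per_month = 1,
    referred_drug = "trastuzumab",
    weekly_doses = data.frame(drug = c("rituximab", "trastuzumab"),
                              doses_per_week = c(12, 20)),
    iv_prep_min_per_dose = 25,
    sc_prep_min_per_dose = 5,
    regional_dose_share = 0.1,
    flags = flags,
    n_port_a_cath_iv = 40, n_picc_sc = 10,
    device_time_iv = 12000, device_time_sc = 1800)
}

# Truncated-normal job duration sampler for the occupancy oracle.
duration_sampler <- function(mean_min = 100, sd_min = 10, floor_min = 30) {
  function(n) pmax(floor_min, stats::rnorm(n, mean_min, sd_min))
}
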