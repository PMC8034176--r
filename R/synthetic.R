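# Synthetic hospital generator. Resources and conversion rates are drawn
# uniformly within configured ranges (the conversion ranges default to the
# per-phase ranges observed across the study hospitals); per-visit stage
# times are drawn from zero-truncated normal distributions centered on the
# reference cycle times with a configurable coefficient of variation.
# Ranges and maximum-entropy-style distribution choices are discussed in the
# methods vignette.

#' Generator configuration
#'
#' Ranges and noise levels for [sample_hospital()] and [generate_cohort()].
#' All ranges are `c(low, high)` with `low <= high`; conversion-rate ranges
#' must lie within \[0, 1\].
#'
#' @param n_hospitals Cohort size.
#' @param seed Integer master seed; per-hospital substreams are derived from
#'   it deterministically, so cohorts are order-stable.
#' @param preset `"study_mix"` gives the observed service mix of the 10
#'   study sites (7 hospitals with both drugs, 2 trastuzumab-only, 1
#'   rituximab-only); `"all_both"` gives every hospital both drugs.
#' @param stage_cv Coefficient of variation of the zero-truncated normal
#'   stage-time noise (0 reproduces the reference times exactly).
#' @param resources Named list of ranges: `opening_min`, `chairs`,
#'   `admin_days`, `treatments_per_day`, `hood_min`, `hood_days`, `hoods`,
#'   `preps_per_week`.
#' @param conversion Nested list `drug -> phase -> c(low, high)` of current
#'   SC-share ranges.
#' @param patients Named list of ranges for per-drug/phase patient counts
#'   and visit rates.
#' @param flag_prevalence Named probabilities that each efficiency process is
#'   already implemented.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_hospitals = 10, seed = 1,
                             preset = c("study_mix", "all_both"),
                             stage_cv = 0.10,
                             resources = list(
                               opening_min = c(540, 720),
                               chairs = c(10, 30),
                               admin_days = c(20, 22),
                               treatments_per_day = c(40, 120),
                               hood_min = c(420, 600),
                               hood_days = c(5, 5),
                               hoods = c(1, 3),
                               preps_per_week = c(100, 300)),
                             conversion = list(
                               rituximab = list(combo = c(0, 0.533),
                                                maintenance = c(0.362, 1)),
                               trastuzumab = list(combo = c(0, 0.917),
                                                  maintenance = c(0.398, 1))),
                             patients = list(
                               n_rituximab = c(20, 120),
                               n_trastuzumab = c(30, 150),
                               combo_share = c(0.25, 0.40),
                               visits_combo = c(1, 2),
                               visits_maintenance = c(0.5, 1)),
                             flag_prevalence = c(
                               dedicated_sc_chair = 0.8,
                               premed_in_waiting_room = 0.875,
                               regional_referral = 0.1,
                               prep_outside_hood = 0.2,
                               avoid_venous_device = 0.778)) {
  preset <- match.arg(preset)
  chk_range <- function(r, name, unit_interval = FALSE) {
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop_invariant("range ", name, " must be c(low, high) with low <= high")
    }
    if (unit_interval && (r[1L] < 0 || r[2L] > 1)) {
      stop_invariant("range ", name, " must lie within [0, 1]")
    }
  }
  for (nm in names(resources)) chk_range(resources[[nm]], nm)
  for (d in names(conversion)) {
    for (ph in names(conversion[[d]])) {
      chk_range(conversion[[d]][[ph]], paste(d, ph), unit_interval = TRUE)
    }
  }
  for (nm in names(patients)) chk_range(patients[[nm]], nm)
  if (stage_cv < 0) stop_invariant("stage_cv must be >= 0")
  structure(list(n_hospitals = n_hospitals, seed = as.integer(seed),
                 preset = preset, stage_cv = stage_cv,
                 resources = resources, conversion = conversion,
                 patients = patients, flag_prevalence = flag_prevalence),
            class = "generator_config")
}

# Zero-truncated normal draws; cv = 0 degenerates to the center.
rnorm_trunc0 <- function(n, center, cv) {
  if (cv == 0 || center == 0) return(rep(center, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), center, cv * center)
    todo <- todo[out[todo] <= 0]
  }
  out
}

runi <- function(r) stats::runif(1L, r[1L], r[2L])
runi_int <- function(r) as.numeric(sample(seq(r[1L], r[2L]), 1L))

# Deterministic per-hospital substream seed, kept inside 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Draw one synthetic hospital
#'
#' Samples a complete [hospital_profile()]: resources uniform within ranges,
#' per-phase current SC shares uniform within the observed study ranges,
#' stage times zero-truncated normal around the reference cycle times, and
#' efficiency-process flags Bernoulli with the observed prevalences.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for this hospital's substream.
#' @param drugs Drugs the hospital administers.
#' @param hospital_id Identifier.
#' @return A [hospital_profile()].
#' @export
sample_hospital <- function(config, seed, drugs = c("rituximab", "trastuzumab"),
                            hospital_id = paste0("H", seed)) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  rs <- config$resources
  res <- unit_resources(
    admin_opening_min_per_day = round(runi(rs$opening_min)),
    admin_days_per_month = runi_int(rs$admin_days),
    n_chairs = runi_int(rs$chairs),
    admin_treatments_per_day = runi_int(rs$treatments_per_day),
    hood_opening_min_per_day = round(runi(rs$hood_min)),
    hood_days_per_week = runi_int(rs$hood_days),
    n_hoods = runi_int(rs$hoods),
    preparations_per_week = runi_int(rs$preps_per_week))

  # noisy cycle-time profiles around the reference centers
  prof <- as.data.frame(reference_cycle_times())
  for (s in STAGES) {
    prof[[s]] <- vapply(prof[[s]], function(m) {
      rnorm_trunc0(1L, m, config$stage_cv)
    }, numeric(1L))
  }
  prof <- cycle_profiles(prof)

  pc <- config$patients
  pats <- NULL
  for (d in drugs) {
    n_total <- runi_int(pc[[paste0("n_", d)]])
    combo_share <- runi(pc$combo_share)
    n_combo <- round(n_total * combo_share)
    n_maint <- n_total - n_combo
    cv <- config$conversion[[d]]
    pats <- rbind(pats, data.frame(
      drug = d, phase = c("combo", "maintenance"),
      n_patients = c(n_combo, n_maint),
      visits_per_month = c(runi(pc$visits_combo), runi(pc$visits_maintenance)),
      sc_fraction = c(runi(cv$combo), runi(cv$maintenance))))
  }

  flags <- process_flags(
    dedicated_sc_chair = stats::runif(1L) < config$flag_prevalence[["dedicated_sc_chair"]],
    premed_in_waiting_room = "rituximab" %in% drugs &&
      stats::runif(1L) < config$flag_prevalence[["premed_in_waiting_room"]],
    regional_referral = stats::runif(1L) < config$flag_prevalence[["regional_referral"]],
    prep_outside_hood = stats::runif(1L) < config$flag_prevalence[["prep_outside_hood"]],
    avoid_venous_device = "trastuzumab" %in% drugs &&
      stats::runif(1L) < config$flag_prevalence[["avoid_venous_device"]])

  referred <- if (flags[["regional_referral"]]) runi_int(c(1, 10)) else 0
  n_port <- 0; n_picc <- 0; t_iv <- 0; t_sc <- 0
  if ("trastuzumab" %in% drugs) {
    n_port <- runi_int(c(10, 60))
    n_picc <- round(n_port * stats::runif(1L, 0.1, 0.4))
    t_iv <- n_port * stats::runif(1L, 250, 400)
    t_sc <- n_picc * stats::runif(1L, 100, 200)
  }

  hospital_profile(
    hospital_id = hospital_id,
    drugs = drugs,
    resources = res,
    patients = pats,
    premed_chair_min = runi(c(20, 45)),
    n_referred_patients = referred,
    referred_visits_per_month = if (referred > 0) runi(c(0.5, 1.5)) else 0,
    referred_drug = if ("trastuzumab" %in% drugs) "trastuzumab" else "rituximab",
    weekly_doses = data.frame(drug = drugs,
                              doses_per_week = vapply(drugs, function(d)
                                runi_int(c(10, 60)), numeric(1L))),
    iv_prep_min_per_dose = runi(c(15, 30)),
    sc_prep_min_per_dose = runi(c(3, 8)),
    regional_dose_share = if (referred > 0) runi(c(0.05, 0.2)) else 0,
    flags = flags,
    n_port_a_cath_iv = n_port, n_picc_sc = n_picc,
    device_time_iv = t_iv, device_time_sc = t_sc,
    profiles = prof)
}

#' Generate a synthetic hospital cohort
#'
#' Draws `n_hospitals` independent hospitals, each from a deterministic
#' substream of the master seed, so the same configuration always reproduces
#' the same cohort and hospitals are order-stable.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_cohort` of [hospital_profile()]s, with
#'   attributes `seed` and `config` recording provenance.
#' @examples
#' cohort <- generate_cohort(generator_config(n_hospitals = 3, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_hospitals
  if (n < 1) stop_invariant("n_hospitals must be >= 1")
  drug_mix <- if (config$preset == "study_mix" && n >= 3) {
    n_both <- round(n * 0.7)
    n_tra <- max(1L, round(n * 0.2))
    n_rit <- n - n_both - n_tra
    if (n_rit < 1) { n_both <- n_both - 1L; n_rit <- 1L }
    c(rep(list(c("rituximab", "trastuzumab")), n_both),
      rep(list("trastuzumab"), n_tra),
      rep(list("rituximab"), n_rit))
  } else {
    rep(list(c("rituximab", "trastuzumab")), n)
  }
  hospitals <- lapply(seq_len(n), function(i) {
    sample_hospital(config, child_seed(config$seed, i),
                    drugs = drug_mix[[i]],
                    hospital_id = sprintf("H%02d", i))
  })
  structure(hospitals, class = "synthetic_cohort",
            seed = config$seed, config = config)
}
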