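test_that("the maximal scenario sets SmPC caps and enables every process", {
  s <- max_conversion_scenario()
  expect_equal(unname(s$sc_dose_fraction), c(0.45, 0.91))
  expect_true(all(s$flags))
  expect_equal(max_conversion_scenario("rituximab")$sc_dose_fraction[["rituximab"]],
               0.45)
  expect_equal(max_conversion_scenario("trastuzumab")$sc_dose_fraction[["trastuzumab"]],
               0.91)
  expect_error(max_conversion_scenario("bevacizumab"),
               class = "sccapacity_config_error")
  # constructing it twice gives the same scenario, and applying it twice to
  # the same hospital gives identical activity
  h <- toy_hospital()
  expect_identical(max_conversion_scenario(), max_conversion_scenario())
  expect_identical(apply_scenario(h, max_conversion_scenario()),
                   apply_scenario(h, max_conversion_scenario()))
})

test_that("fractions above their cap are rejected", {
  expect_error(conversion_scenario(c(rituximab = 0.5)),
               class = "sccapacity_invariant_error")
  expect_error(conversion_scenario(c(trastuzumab = -0.1)),
               class = "sccapacity_invariant_error")
  expect_silent(conversion_scenario(c(rituximab = 0.45, trastuzumab = 0.91)))
})

test_that("applying the current fractions reproduces observed activity", {
  h <- toy_hospital(sc_combo = 0.2, sc_maint = 0.4)
  f_cur_r <- with(subset(h$patients, drug == "rituximab"),
                  sum(n_patients * sc_fraction) / sum(n_patients))
  f_cur_t <- with(subset(h$patients, drug == "trastuzumab"),
                  sum(n_patients * sc_fraction) / sum(n_patients))
  s <- conversion_scenario(c(rituximab = f_cur_r, trastuzumab = f_cur_t),
                           flags = h$flags)
  act <- apply_scenario(h, s)
  expect_equal(act$conversions$n_converted,
               h$patients$n_patients * h$patients$sc_fraction,
               tolerance = 1e-12)
})

test_that("doubling the scenario fraction doubles converted counts until capped", {
  h <- toy_hospital(sc_combo = 0.1, sc_maint = 0.2)
  f_cur <- function(d) with(subset(h$patients, drug == d),
                            sum(n_patients * sc_fraction) / sum(n_patients))
  s1 <- conversion_scenario(c(rituximab = f_cur("rituximab"),
                              trastuzumab = f_cur("trastuzumab")),
                            flags = h$flags)
  s2 <- conversion_scenario(c(rituximab = 2 * f_cur("rituximab"),
                              trastuzumab = 2 * f_cur("trastuzumab")),
                            flags = h$flags)
  a1 <- apply_scenario(h, s1)
  a2 <- apply_scenario(h, s2)
  expect_equal(a2$conversions$n_converted, 2 * a1$conversions$n_converted,
               tolerance = 1e-9)
  # never beyond the treated population
  full <- apply_scenario(h, max_conversion_scenario())
  expect_true(all(full$conversions$n_converted <= h$patients$n_patients + 1e-9))
})

test_that("a below-cap scenario under current practice is rejected, at-cap is a no-op", {
  h <- toy_hospital(sc_combo = 0.3, sc_maint = 0.6)  # rituximab share ~0.48
  expect_error(apply_scenario(h, conversion_scenario(
    c(rituximab = 0.10), flags = h$flags)),
    class = "sccapacity_config_error")
  # the rituximab share exceeds the 0.45 cap: the maximal scenario keeps it
  act <- apply_scenario(h, max_conversion_scenario())
  rit <- act$conversions$drug == "rituximab"
  expect_equal(act$conversions$n_converted[rit],
               h$patients$n_patients[rit] * h$patients$sc_fraction[rit],
               tolerance = 1e-9)
})

test_that("process flags gate premedication, referral and relocation", {
  h <- toy_hospital()
  off <- conversion_scenario(c(rituximab = 0.45, trastuzumab = 0.91),
                             flags = process_flags())
  act <- apply_scenario(h, off)
  expect_equal(act$n_premed_patients, 0)
  expect_equal(act$n_referred_patients, 0)
  expect_equal(act$doses_prepared_regionally_per_week, 0)
  expect_false(act$prep_relocated_to_unit)
  res <- evaluate_hospital(h, off)
  expect_equal(res$impacts$P2$pct_increase, 0)
  expect_equal(res$impacts$P3_admin$pct_increase, 0)
  expect_equal(res$impacts$P3_prep$pct_increase, 0)
  expect_equal(res$impacts$P4b$pct_increase, 0)
  expect_gt(res$impacts$P1$pct_increase, 0)
  expect_gt(res$impacts$P4a$pct_increase, 0)
})

test_that("a hospital with no SC activity under a zero scenario has zero impacts", {
  h <- toy_hospital(sc_combo = 0, sc_maint = 0, flags = process_flags())
  s <- conversion_scenario(c(rituximab = 0, trastuzumab = 0),
                           flags = process_flags())
  res <- evaluate_hospital(h, s)
  for (p in c("P1", "P2", "P3_admin", "P3_prep", "P4a", "P4b")) {
    expect_equal(res$impacts[[p]]$pct_increase, 0, info = p)
  }
  tr <- res$table
  expect_equal(tr$value[tr$parameter == "time_reduction_rituximab"], 0)
})

test_that("evaluate_hospital matches a spreadsheet-style hand calculation", {
  h <- toy_hospital(sc_combo = 0.2, sc_maint = 0.4)
  s <- max_conversion_scenario()
  res <- evaluate_hospital(h, s)

  # P1 by hand: target fractions scale 0.2/0.4 by 0.45/f_cur (rituximab)
  # and 0.91/f_cur (trastuzumab), converted counts x visits x chair deltas
  hand_p1 <- local({
    mins <- 0
    for (d in c("rituximab", "trastuzumab")) {
      p <- subset(h$patients, drug == d)
      f_cur <- sum(p$n_patients * p$sc_fraction) / sum(p$n_patients)
      f_new <- s$sc_dose_fraction[[d]]
      tf <- pmin(1, p$sc_fraction * f_new / f_cur)
      deltas <- c(combo = if (d == "rituximab") 296 - 139 else 162 - 107,
                  maintenance = if (d == "rituximab") 183 - 21 else 64 - 15)
      mins <- mins + sum(p$n_patients * tf * p$visits_per_month *
                           deltas[p$phase])
    }
    mins
  })
  expect_equal(res$impacts$P1$minutes_saved_per_period, hand_p1,
               tolerance = 1e-9)
  avg_admin <- 600 * 10 / 60
  expect_equal(res$impacts$P1$pct_increase,
               100 * (hand_p1 / avg_admin) / (60 * 20), tolerance = 1e-9)

  # P4a by hand: weekly SC doses at scenario fractions minus regional share
  sc_doses <- 12 * 0.45 + 20 * 0.91
  regional <- sc_doses * 0.1
  expect_equal(res$impacts$P4a$minutes_saved_per_period,
               (25 - 5) * (sc_doses - regional), tolerance = 1e-9)
  expect_equal(res$impacts$P4b$minutes_saved_per_period,
               5 * (sc_doses - regional), tolerance = 1e-9)

  # quality side: scenario-weighted monthly time reduction
  tr <- res$table
  expect_equal(tr$value[tr$parameter == "time_reduction_rituximab"],
               round(100 * 0.45 * (411 - 218) / 411, 2))
  expect_equal(tr$value[tr$parameter == "time_reduction_trastuzumab"],
               round(100 * 0.91 * (316 - 212) / 316, 2))
  expect_equal(tr$value[tr$parameter == "productivity_eur_trastuzumab"],
               0.91 * (316 - 212) * 0.205464, tolerance = 1e-9)
  expect_equal(tr$value[tr$parameter == "device_rate_reduction"],
               100 * (40 - 10) / 40)
})

test_that("capacity impacts and time reduction are monotone in the SC fraction", {
  h <- toy_hospital(sc_combo = 0.05, sc_maint = 0.1)
  vals <- lapply(c(0.15, 0.25, 0.35, 0.45), function(f) {
    s <- conversion_scenario(c(rituximab = f, trastuzumab = 2 * f),
                             flags = process_flags(TRUE, TRUE, TRUE, TRUE, TRUE))
    evaluate_hospital(h, s)$table
  })
  for (p in c("P1", "P2", "P4a", "P4b", "capacity_pct_sum",
              "time_reduction_rituximab", "time_reduction_trastuzumab")) {
    series <- vapply(vals, function(tb) tb$value[tb$parameter == p],
                     numeric(1))
    expect_true(all(diff(series) >= -1e-9), info = p)
  }
})

test_that("aggregation is the unweighted mean, permutation-invariant, NA-excluding", {
  h <- toy_hospital()
  s <- max_conversion_scenario()
  r1 <- evaluate_hospital(h, s)
  # identical hospitals: aggregate equals each
  agg <- aggregate_hospitals(list(r1, r1, r1))
  expect_equal(agg$mean_value[agg$parameter == "P1"],
               r1$table$value[r1$table$parameter == "P1"])

  # two synthetic values +2 and +4 average to +3
  r2 <- r1
  r2$table$value[r2$table$parameter == "P1"] <- 2
  r3 <- r1
  r3$table$value[r3$table$parameter == "P1"] <- 4
  agg23 <- aggregate_hospitals(list(r2, r3))
  expect_equal(agg23$mean_value[agg23$parameter == "P1"], 3)

  # random cohort vs brute-force mean, and permutation invariance
  cohort <- generate_cohort(generator_config(n_hospitals = 6, seed = 9))
  res <- lapply(cohort, evaluate_hospital, scenario = s)
  agg_f <- aggregate_hospitals(res)
  agg_r <- aggregate_hospitals(rev(res))
  expect_equal(agg_f, agg_r)
  for (p in agg_f$parameter) {
    vals <- vapply(res, function(r) r$table$value[r$table$parameter == p],
                   numeric(1))
    expect_equal(agg_f$mean_value[agg_f$parameter == p],
                 mean(vals, na.rm = TRUE), info = p)
    expect_equal(agg_f$n_hospitals[agg_f$parameter == p], sum(!is.na(vals)))
  }
  # hospitals without a drug are excluded from that drug's quality means
  mix_cohort <- generate_cohort(generator_config(n_hospitals = 10, seed = 5,
                                                 preset = "study_mix"))
  res_mix <- lapply(mix_cohort, evaluate_hospital, scenario = s)
  agg_mix <- aggregate_hospitals(res_mix)
  expect_equal(agg_mix$n_hospitals[agg_mix$parameter == "time_reduction_rituximab"], 8)
  expect_equal(agg_mix$n_hospitals[agg_mix$parameter == "time_reduction_trastuzumab"], 9)
  expect_error(aggregate_hospitals(list()),
               class = "sccapacity_invariant_error")
})
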