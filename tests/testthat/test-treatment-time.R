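ref_prof <- reference_cycle_times()

test_that("per-cycle totals are exact component sums", {
  expect_equal(cycle_total(stage_times(71, 296, 20)), 387)
  expect_equal(cycle_total(stage_times(60, 15, 16)), 91)
  expect_equal(cycle_total(stage_times(53, 21, 15)), 89)
  expect_equal(cycle_total(stage_times(0, 0, 0)), 0)
  expect_error(stage_times(-1, 10, 10), class = "sccapacity_invariant_error")
  expect_error(stage_times(Inf, 10, 10), class = "sccapacity_invariant_error")
})

test_that("annual patient time sums the right profile over every cycle", {
  # first-line follicular lymphoma, all-IV: 8 x 387 + 12 x 267
  fl <- reference_schedules("rituximab")
  ann <- annual_patient_time(fl[fl$indication_id == "fl_first_line", ],
                             ref_prof, "rituximab", "IV")
  expect_equal(sum(ann), 8 * 387 + 12 * 267)

  # trastuzumab all-IV year: component-sum first cycle (287), 7 combo, 10 maint
  tz <- reference_schedules("trastuzumab")
  ann_t <- annual_patient_time(tz, ref_prof, "trastuzumab", "IV")
  expect_equal(sum(ann_t), 287 + 7 * 264 + 10 * 166)

  # SC pathway with first-cycle-IV rule: exactly one combo cycle at IV times
  ann_sc <- annual_patient_time(fl[fl$indication_id == "dlbcl", ],
                                ref_prof, "rituximab", "SC")
  expect_equal(ann_sc[["chair_min"]], 296 + 7 * 139)

  empty <- regimen_schedules(data.frame(
    indication_id = "none", n_loading_cycles = 0, n_combo_cycles = 0,
    n_maintenance_cycles = 0, first_cycle_always_iv = TRUE))
  expect_equal(unname(annual_patient_time(empty, ref_prof, "rituximab", "IV")),
               c(0, 0, 0))
})

test_that("a missing profile raises a configuration error naming the triple", {
  prof_iv_only <- cycle_profiles(
    subset(as.data.frame(ref_prof), route == "IV"))
  err <- expect_error(
    annual_patient_time(reference_schedules("trastuzumab"), prof_iv_only,
                        "trastuzumab", "SC"),
    class = "sccapacity_config_error")
  expect_match(conditionMessage(err), "trastuzumab, SC, loading_combo")
})

test_that("weighted monthly times reproduce the reference table cells", {
  cases <- list(
    list("rituximab", "IV", c(86, 302, 23), 411),
    list("rituximab", "SC", c(78, 118, 22), 218),
    list("trastuzumab", "IV", c(127, 163, 26), 316),
    list("trastuzumab", "SC", c(106, 82, 24), 212))
  for (cs in cases) {
    m <- weighted_monthly_time(reference_case_mix(cs[[1]]),
                               reference_schedules(cs[[1]]),
                               ref_prof, cs[[1]], cs[[2]])
    expect_equal(unname(m$stage_monthly_rounded), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
    expect_equal(m$total_rounded, cs[[4]], info = paste(cs[[1]], cs[[2]]))
    # total is the sum of rounded stages, and rounding is half-to-even
    expect_identical(m$total_rounded, sum(m$stage_monthly_rounded))
    expect_identical(m$stage_monthly_rounded, round(m$stage_monthly_unrounded))
  }
  # the rounded-stage convention is visible in the SC totals: 217.44 -> 218
  sc <- weighted_monthly_time(reference_case_mix("rituximab"),
                              reference_schedules("rituximab"),
                              ref_prof, "rituximab", "SC")
  expect_equal(sc$total_unrounded, 217.4433, tolerance = 1e-6)
  # and in the half-to-even stage cells: 106.5 -> 106 but 25.5 -> 26
  tz_sc <- weighted_monthly_time(reference_case_mix("trastuzumab"),
                                 reference_schedules("trastuzumab"),
                                 ref_prof, "trastuzumab", "SC")
  expect_equal(tz_sc$stage_monthly_unrounded[["waiting_min"]], 106.5)
  expect_equal(tz_sc$stage_monthly_rounded[["waiting_min"]], 106)
  tz_iv <- weighted_monthly_time(reference_case_mix("trastuzumab"),
                                 reference_schedules("trastuzumab"),
                                 ref_prof, "trastuzumab", "IV")
  expect_equal(tz_iv$stage_monthly_unrounded[["consultation_min"]], 25.5)
  expect_equal(tz_iv$stage_monthly_rounded[["consultation_min"]], 26)
})

test_that("weighted monthly time agrees with a cycle-by-cycle enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    prof <- perturbed_profiles()
    for (d in c("rituximab", "trastuzumab")) {
      for (r in c("IV", "SC")) {
        m <- weighted_monthly_time(reference_case_mix(d),
                                   reference_schedules(d), prof, d, r)
        oracle <- brute_monthly_time(reference_case_mix(d),
                                     reference_schedules(d), prof, d, r)
        expect_equal(unname(m$stage_monthly_unrounded), oracle,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("unrounded monthly stages conserve annual minutes exactly", {
  mix <- reference_case_mix("rituximab")
  sch <- reference_schedules("rituximab")
  m <- weighted_monthly_time(mix, sch, ref_prof, "rituximab", "SC")
  acc <- stats::setNames(numeric(3),
                         c("waiting_min", "chair_min", "consultation_min"))
  for (k in seq_len(nrow(mix))) {
    acc <- acc + mix$share[k] *
      annual_patient_time(sch[sch$indication_id == mix$indication_id[k], ],
                          ref_prof, "rituximab", "SC")
  }
  expect_identical(m$stage_monthly_unrounded * 12, acc)
})

test_that("weighted monthly stages are monotone in any profile stage time", {
  set.seed(21)
  base <- weighted_monthly_time(reference_case_mix("rituximab"),
                                reference_schedules("rituximab"),
                                ref_prof, "rituximab", "SC")
  df <- as.data.frame(ref_prof)
  for (i in sample(nrow(df), 5)) {
    for (s in c("waiting_min", "chair_min", "consultation_min")) {
      bumped <- df
      bumped[i, s] <- bumped[i, s] + runif(1, 1, 60)
      m <- weighted_monthly_time(reference_case_mix("rituximab"),
                                 reference_schedules("rituximab"),
                                 cycle_profiles(bumped), "rituximab", "SC")
      expect_true(all(m$stage_monthly_unrounded >=
                        base$stage_monthly_unrounded - 1e-12))
    }
  }
})

test_that("a uniform 12-cycle schedule yields monthly total = cycle total", {
  prof <- cycle_profiles(data.frame(
    drug = "rituximab", route = c("IV", "SC"), phase = "combo",
    waiting_min = 10, chair_min = 40, consultation_min = 5))
  sch <- regimen_schedules(data.frame(
    indication_id = "uniform", n_loading_cycles = 0, n_combo_cycles = 12,
    n_maintenance_cycles = 0, first_cycle_always_iv = FALSE))
  mix <- case_mix(data.frame(indication_id = "uniform", share = 1))
  m <- weighted_monthly_time(mix, sch, prof, "rituximab", "IV")
  expect_equal(m$total_rounded, 55)
})

test_that("monthly time reduction matches the headline percentages", {
  for (d in c("rituximab", "trastuzumab")) {
    iv <- weighted_monthly_time(reference_case_mix(d),
                                reference_schedules(d), ref_prof, d, "IV")
    sc <- weighted_monthly_time(reference_case_mix(d),
                                reference_schedules(d), ref_prof, d, "SC")
    red <- monthly_time_reduction(iv, sc)
    if (d == "rituximab") {
      expect_equal(red$total_pct, 46.96)
    } else {
      expect_equal(red$total_pct, 32.91)
    }
    # decomposition covers the whole reduction
    expect_equal(sum(red$stage_delta_min),
                 iv$total_rounded - sc$total_rounded)
  }
})

test_that("degenerate reductions are handled explicitly", {
  iv <- weighted_monthly_time(reference_case_mix("rituximab"),
                              reference_schedules("rituximab"),
                              ref_prof, "rituximab", "IV")
  expect_equal(monthly_time_reduction(iv, iv)$total_pct, 0)
  sc <- weighted_monthly_time(reference_case_mix("trastuzumab"),
                              reference_schedules("trastuzumab"),
                              ref_prof, "trastuzumab", "SC")
  expect_error(monthly_time_reduction(iv, sc),
               class = "sccapacity_invariant_error")
})

test_that("case-mix shares must sum to one", {
  expect_error(case_mix(data.frame(indication_id = c("a", "b"),
                                   share = c(0.5, 0.4))),
               class = "sccapacity_invariant_error")
  expect_error(case_mix(data.frame(indication_id = "a", share = 1.2)),
               class = "sccapacity_invariant_error")
})
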