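#!/usr/bin/env Rscript
# Draws the 10-hospital synthetic cohort used by the scenario analysis
# (service mix: 7 hospitals with both drugs, 2 trastuzumab-only,
# 1 rituximab-only) and summarises its profiles.

suppressPackageStartupMessages(library(sccapacity))

seed <- 20
cohort <- generate_cohort(generator_config(n_hospitals = 10, seed = seed,
                                           preset = "study_mix"))
dir.create("results", showWarnings = FALSE)

summ <- do.call(rbind, lapply(cohort, function(h) {
  p <- h$patients
  sc_share <- function(d) {
    q <- p[p$drug == d, ]
    if (!nrow(q)) return(NA_real_)
    round(sum(q$n_patients * q$sc_fraction) / sum(q$n_patients), 3)
  }
  data.frame(hospital_id = h$hospital_id,
             drugs = paste(h$drugs, collapse = "+"),
             chairs = h$resources$n_chairs,
             hoods = h$resources$n_hoods,
             treatments_per_day = h$resources$admin_treatments_per_day,
             preps_per_week = h$resources$preparations_per_week,
             sc_share_rituximab = sc_share("rituximab"),
             sc_share_trastuzumab = sc_share("trastuzumab"),
             n_processes = sum(h$flags))
}))
cat("Synthetic cohort (seed", seed, "):\n")
print(summ, row.names = FALSE)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)

cat("\nCurrent SC shares fall inside the observed study ranges by",
    "construction;\nresources vary independently of conversion rates.\n")
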