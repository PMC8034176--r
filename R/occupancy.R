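# Minute-resolution occupancy simulation of a bank of identical servers
# (administration chairs, or laminar-flow hoods) over one operating window.
# Used as an independent oracle for the analytic capacity formulas: at
# saturation, the maximum number of jobs packed greedily into the window
# should change, under a given amount of minutes saved, by about the
# analytic additional-treatments estimate.

#' Greedy occupancy simulation
#'
#' Packs jobs with the given durations onto `n_servers` identical servers
#' within an opening window, assigning each job in order to the
#' earliest-free server; a job that cannot finish before closing is turned
#' away (and every later job is still tried). Returns the number of
#' completed jobs and occupancy statistics.
#'
#' @param opening_min Minutes the unit is open.
#' @param n_servers Number of chairs or hoods.
#' @param durations_min Numeric vector of job durations (minutes), in
#'   arrival order.
#' @return List: `n_treated`, `busy_min` (total server-busy minutes),
#'   `mean_occupancy_min` (busy minutes per treated job), `utilization`.
#' @examples
#' simulate_occupancy(600, 2, rep(100, 20))$n_treated  # 12
#' @export
simulate_occupancy <- function(opening_min, n_servers, durations_min) {
  if (opening_min <= 0 || n_servers < 1) {
    stop_invariant("opening minutes must be > 0 and servers >= 1")
  }
  if (any(durations_min <= 0)) stop_invariant("durations must be > 0")
  free_at <- numeric(n_servers)
  treated <- 0L
  busy <- 0
  for (d in durations_min) {
    i <- which.min(free_at)
    if (free_at[i] + d <= opening_min) {
      free_at[i] <- free_at[i] + d
      treated <- treated + 1L
      busy <- busy + d
    }
  }
  list(n_treated = treated, busy_min = busy,
       mean_occupancy_min = if (treated > 0) busy / treated else NA_real_,
       utilization = busy / (opening_min * n_servers))
}

#' Simulated capacity gain from shortened treatments
#'
#' Oracle counterpart of the analytic additional-treatments estimate: packs
#' a saturating stream of jobs into the window, then repeats with
#' `n_shortened` of the jobs shortened by `delta_min` each (the SC
#' conversions) and the same unlimited job stream behind them, and reports
#' the gain in completed jobs.
#'
#' @param opening_min,n_servers As in [simulate_occupancy()].
#' @param duration_sampler Function `n -> n durations` for ordinary jobs.
#' @param n_shortened Number of jobs shortened.
#' @param delta_min Minutes removed from each shortened job.
#' @param n_offer Number of jobs offered (must saturate the unit).
#' @return List: `baseline` and `scenario` simulation results,
#'   `extra_treatments` (scenario minus baseline counts) and
#'   `minutes_saved` (`n_shortened * delta_min`).
#' @export
simulated_capacity_gain <- function(opening_min, n_servers, duration_sampler,
                                    n_shortened, delta_min,
                                    n_offer = 10 * n_servers) {
  durations <- duration_sampler(n_offer)
  base <- simulate_occupancy(opening_min, n_servers, durations)
  short <- durations
  idx <- seq_len(min(n_shortened, length(short)))
  short[idx] <- pmax(1, short[idx] - delta_min)
  scen <- simulate_occupancy(opening_min, n_servers, short)
  list(baseline = base, scenario = scen,
       extra_treatments = scen$n_treated - base$n_treated,
       minutes_saved = n_shortened * delta_min)
}
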