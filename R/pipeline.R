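# End-to-end two-arm cost-effectiveness run: cohort -> screening ->
# lifetime progression in both arms -> discounted accrual -> ICER.

#' Run the two-arm screening cost-effectiveness analysis
#'
#' Generates (or takes) a screening-eligible cohort, applies the
#' one-time screening program, simulates lifetime disease progression of
#' every true (undiagnosed) diabetes case under both arms, accrues
#' discounted costs and QALYs, and computes the incremental
#' cost-effectiveness of screening relative to no screening. All
#' reported quantities are per true case of diabetes; screening and
#' confirmation costs of the whole screened population (including
#' disease-free screens and false-positive confirmations) are amortized
#' over the true cases.
#'
#' @param params a `dm_params` bundle (e.g. [brazil_params()])
#' @param cohort optional pre-built `dm_cohort`; default generated from
#'   `surface`
#' @param surface prevalence surface (default
#'   [brazil_prevalence_surface()])
#' @param cohort_size cohort size when generating (default 100,000; the
#'   per-case results are invariant to it in expected mode)
#' @param mode cohort mode, `"expected"` (deterministic) or `"sampled"`
#' @param seed RNG seed for sampled cohorts
#' @param life_table a `dm_life_table` (default [generate_life_table()])
#' @param comparator_intensive do diagnosed persons in the *unscreened*
#'   arm receive intensified control? (default TRUE, the base case;
#'   FALSE is the no-intensive-control comparator scenario)
#' @param keep_trajectories retain the per-cycle trajectories in the
#'   result (default FALSE; they are sizeable)
#' @return a `dm_cea` list: `screening` outcome, `ledgers`
#'   (`screened`, `unscreened`), `ce` (a `dm_ce_result`), `summary`
#'   (three-row table, see [ce_summary()]), `incidence` (lifetime
#'   cumulative complication incidence per arm, %), `n_cases`
#' @export
run_cea <- function(params, cohort = NULL,
                    surface = brazil_prevalence_surface(),
                    cohort_size = 1e5, mode = "expected", seed = 1L,
                    life_table = generate_life_table(),
                    comparator_intensive = TRUE,
                    keep_trajectories = FALSE) {
  validate_params(params)
  if (is.null(cohort)) {
    # screening-module onset convention: undiagnosed cases have had
    # diabetes for lead_time - detection_benefit years at screening, so
    # detection at screening advances diagnosis by the detection benefit
    sc <- params$screening
    cohort <- generate_cohort(
      surface, cohort_size, mode, seed,
      lead_time_years = sc$lead_time_years,
      onset_years_at_screening =
        sc$lead_time_years - sc$detection_benefit_years)
  }
  scr <- screen_cohort(cohort, params$screening)
  traj_s <- simulate_lifetime(scr$cohort, "screened", params, life_table,
                              intensive = TRUE)
  traj_u <- simulate_lifetime(cohort, "unscreened", params, life_table,
                              intensive = comparator_intensive)
  led_s <- accrue(traj_s, params$costs, params$utilities, params$settings,
                  screening_cost = scr$outcome$screening_cost_total +
                    scr$outcome$confirmation_cost_total,
                  label = "screening")
  led_u <- accrue(traj_u, params$costs, params$utilities, params$settings,
                  screening_cost = 0, label = "no_screening")
  ce <- compute_icer(led_s, led_u)
  out <- list(
    screening = scr$outcome,
    ledgers = list(screened = led_s, unscreened = led_u),
    ce = ce,
    summary = ce_summary(led_s, led_u),
    incidence = list(screened = cumulative_incidence(traj_s),
                     unscreened = cumulative_incidence(traj_u)),
    n_cases = led_s$n_cases
  )
  if (keep_trajectories) {
    out$trajectories <- list(screened = traj_s, unscreened = traj_u)
  }
  structure(out, class = "dm_cea")
}

#' @export
print.dm_cea <- function(x, ...) {
  cat("<dm_cea> two-arm screening cost-effectiveness run\n")
  cat(sprintf("  true cases: %.1f | screened: %.0f (%.1f%% positive)\n",
              x$n_cases, x$screening$n_screened,
              100 * x$screening$n_positive / x$screening$n_screened))
  print(x$ce)
  inc <- rbind(unscreened = x$incidence$unscreened,
               screened = x$incidence$screened)
  cat("  lifetime cumulative incidence (%):\n")
  print(round(inc, 2))
  invisible(x)
}

#' Export a trajectory as long-format CSV
#'
#' One row per stratum, cycle and quantity (occupancy, event or death
#' mass), with the stratum table joined in.
#'
#' @param trajectory a `dm_trajectory`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  qcols <- setdiff(names(df), c("stratum_id", "cycle", "age", "treated",
                                "ysd", "ht"))
  long <- do.call(rbind, lapply(qcols, function(cn) {
    data.frame(stratum_id = df$stratum_id, cycle = df$cycle, age = df$age,
               quantity = cn, mass = df[[cn]])
  }))
  long <- long[order(long$stratum_id, long$cycle, long$quantity), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
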