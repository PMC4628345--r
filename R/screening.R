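# One-time capillary glucose screening front-end: classify undiagnosed
# cases by test result, clear false positives at confirmation, and charge
# screening / confirmation costs.

#' Screen a cohort
#'
#' Applies the one-time screening test to the policy's target population
#' (everyone aged 40+, or hypertensive persons only). Undiagnosed
#' diabetes mass splits into true positives (`sensitivity`) and false
#' negatives; disease-free mass splits into false positives
#' (`1 - specificity`) and true negatives. Every screened person incurs
#' the per-screen cost; every screen-positive incurs the confirmatory
#' work-up cost (an extra fasting plasma glucose test plus physician
#' visits). Confirmation clears false positives, so no false diagnoses
#' persist and false positives carry no downstream utility decrement.
#' True positives are marked `detected`; their diagnosis is advanced by
#' the policy's detection benefit when the cohort is simulated with
#' [simulate_lifetime()]. The four outcome masses partition the screened
#' population exactly.
#'
#' @param cohort a `dm_cohort`
#' @param policy a screening policy block (see [brazil_params()]),
#'   e.g. `params$screening`
#' @return list with `outcome` (a `dm_screening_outcome`: masses
#'   `true_positive`, `false_negative`, `false_positive`,
#'   `true_negative`, plus `n_screened`, `n_positive`,
#'   `screening_cost_total`, `confirmation_cost_total`) and `cohort`
#'   (the cohort with undiagnosed target rows split by `detected`)
#' @export
screen_cohort <- function(cohort, policy) {
  in_target <- if (policy$target == "hypertensive_only") {
    cohort$hypertensive
  } else {
    rep(TRUE, nrow(cohort))
  }
  if (sum(cohort$mass[in_target]) <= 0) {
    stop("screening target subgroup '", policy$target, "' is empty")
  }
  und <- in_target & cohort$diabetes == "undiagnosed"
  free <- in_target & cohort$diabetes == "none"

  tp_mass <- sum(cohort$mass[und]) * policy$sensitivity
  fn_mass <- sum(cohort$mass[und]) * (1 - policy$sensitivity)
  fp_mass <- sum(cohort$mass[free]) * (1 - policy$specificity)
  tn_mass <- sum(cohort$mass[free]) * policy$specificity
  n_screened <- sum(cohort$mass[in_target])
  n_positive <- tp_mass + fp_mass

  out_cohort <- cohort
  out_cohort$detected <- FALSE
  if (any(und)) {
    det <- out_cohort[und, , drop = FALSE]
    det$detected <- TRUE
    det$mass <- det$mass * policy$sensitivity
    out_cohort$mass[und] <- out_cohort$mass[und] * (1 - policy$sensitivity)
    out_cohort <- rbind(out_cohort, det)
    rownames(out_cohort) <- NULL
  }
  out_cohort <- new_dm_cohort(out_cohort, size = attr(cohort, "size"),
                              mode = attr(cohort, "mode"),
                              seed = attr(cohort, "seed"))

  costs <- screening_unit_costs(policy, n_screened, n_positive)
  outcome <- structure(list(
    true_positive = tp_mass, false_negative = fn_mass,
    false_positive = fp_mass, true_negative = tn_mass,
    n_screened = n_screened, n_positive = n_positive,
    screening_cost_total = costs$screening,
    confirmation_cost_total = costs$confirmation
  ), class = "dm_screening_outcome")
  list(outcome = outcome, cohort = out_cohort)
}

#' @export
print.dm_screening_outcome <- function(x, ...) {
  cat("<dm_screening_outcome>\n")
  cat(sprintf("  screened %.0f | positive %.0f (%.1f%%)\n", x$n_screened,
              x$n_positive, 100 * x$n_positive / x$n_screened))
  cat(sprintf("  TP %.1f  FN %.1f  FP %.1f  TN %.1f\n", x$true_positive,
              x$false_negative, x$false_positive, x$true_negative))
  cat(sprintf("  costs: screening %.2f + confirmation %.2f = %.2f US$\n",
              x$screening_cost_total, x$confirmation_cost_total,
              x$screening_cost_total + x$confirmation_cost_total))
  invisible(x)
}

#' Screening and confirmation costs
#'
#' `total = n_screened * cost_per_screen +
#'  n_positive * cost_per_confirmation`.
#'
#' @param policy screening policy block
#' @param n_screened number (mass) of persons screened
#' @param n_positive number (mass) screening positive
#'   (`0 <= n_positive <= n_screened`)
#' @return list with `screening`, `confirmation` and `total` (US$)
#' @export
screening_unit_costs <- function(policy, n_screened, n_positive) {
  if (n_screened < 0 || n_positive < 0) stop("counts must be >= 0")
  if (n_positive > n_screened) stop("n_positive cannot exceed n_screened")
  s <- n_screened * policy$cost_per_screen
  k <- n_positive * policy$cost_per_confirmation
  list(screening = s, confirmation = k, total = s + k)
}
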