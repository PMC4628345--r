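# One-way sensitivity and scenario engine: named perturbations of the
# base-case bundle, each run through the full two-arm pipeline, plus
# tornado-style ranking of paired (low, high) scenarios.

.structural_switches <- c("hypertensive_only_screening",
                          "no_intensive_control_comparator",
                          "macrovascular_benefit_20pct")

#' Define a sensitivity / scenario specification
#'
#' Either a parameter perturbation (a `target` group with a
#' multiplicative `factor` or replacement `value`, see
#' [perturb_params()]) or one of the closed set of structural switches:
#' `hypertensive_only_screening` (restrict the program to hypertensive
#' persons), `no_intensive_control_comparator` (diagnosed persons in the
#' unscreened arm receive standard rather than intensified control) and
#' `macrovascular_benefit_20pct` (intensified glycemic control also
#' reduces CHD and stroke risk by 20%, the metformin-benefit scenario).
#'
#' @param name scenario name (unique within a run)
#' @param target parameter group for [perturb_params()]
#' @param factor multiplicative factor (with `target`)
#' @param value replacement value (with `target`)
#' @param structural one of the structural switches
#' @param group tornado pairing key (scenarios sharing a `group` with
#'   sides `"low"` and `"high"` form one tornado bar)
#' @param side `"low"` or `"high"` within a tornado pair
#' @return a `dm_scenario` spec
#' @export
scenario_spec <- function(name, target = NULL, factor = NULL, value = NULL,
                          structural = NULL, group = NULL, side = NULL) {
  if (is.null(structural) == is.null(target)) {
    stop("scenario '", name,
         "': supply exactly one of a target or a structural switch")
  }
  if (!is.null(structural) && !structural %in% .structural_switches) {
    stop("unknown structural switch '", structural, "'; valid: ",
         paste(.structural_switches, collapse = ", "))
  }
  if (!is.null(factor) && factor <= 0) stop("scenario multipliers must be > 0")
  structure(list(name = name, target = target, factor = factor,
                 value = value, structural = structural,
                 group = group, side = side),
            class = "dm_scenario")
}

apply_scenario <- function(params, spec) {
  comparator_intensive <- TRUE
  if (!is.null(spec$structural)) {
    params <- switch(spec$structural,
      hypertensive_only_screening =
        perturb_params(params, "screening_target", value = "hypertensive_only"),
      no_intensive_control_comparator = {
        comparator_intensive <- FALSE
        params
      },
      macrovascular_benefit_20pct =
        perturb_params(params, "glycemic_macro_rr",
                       value = c(chd = 0.20, stroke = 0.20))
    )
  } else {
    params <- perturb_params(params, spec$target, factor = spec$factor,
                             value = spec$value)
  }
  list(params = params, comparator_intensive = comparator_intensive)
}

#' The shipped one-way sensitivity and scenario set
#'
#' The full battery run around the base case: detection benefit 4 and 6
#' years; screening, intensified glycemic, intensified hypertension and
#' complication costs each +/-20%; discount rates 1% and 10%; utility
#' weights +/-20%; a 20% macrovascular risk reduction from intensified
#' glycemic control applied to CHD only, stroke only, and both; selective
#' screening of hypertensive persons; and a comparator in which
#' non-screened persons never receive intensified control.
#'
#' @return list of `dm_scenario` specs
#' @export
table4_scenarios <- function() {
  list(
    scenario_spec("detection_benefit_4y", target = "detection_benefit_years",
                  value = 4, group = "detection_benefit", side = "low"),
    scenario_spec("detection_benefit_6y", target = "detection_benefit_years",
                  value = 6, group = "detection_benefit", side = "high"),
    scenario_spec("screening_costs_+20", target = "screening_costs",
                  factor = 1.2, group = "screening_costs", side = "high"),
    scenario_spec("screening_costs_-20", target = "screening_costs",
                  factor = 0.8, group = "screening_costs", side = "low"),
    scenario_spec("glycemic_costs_+20", target = "glycemic_treatment_costs",
                  factor = 1.2, group = "glycemic_costs", side = "high"),
    scenario_spec("glycemic_costs_-20", target = "glycemic_treatment_costs",
                  factor = 0.8, group = "glycemic_costs", side = "low"),
    scenario_spec("hypertension_costs_+20",
                  target = "hypertension_treatment_costs", factor = 1.2,
                  group = "hypertension_costs", side = "high"),
    scenario_spec("hypertension_costs_-20",
                  target = "hypertension_treatment_costs", factor = 0.8,
                  group = "hypertension_costs", side = "low"),
    scenario_spec("complication_costs_+20", target = "complication_costs",
                  factor = 1.2, group = "complication_costs", side = "high"),
    scenario_spec("complication_costs_-20", target = "complication_costs",
                  factor = 0.8, group = "complication_costs", side = "low"),
    scenario_spec("discount_1pct", target = "discount_rate", value = 0.01,
                  group = "discount_rate", side = "low"),
    scenario_spec("discount_10pct", target = "discount_rate", value = 0.10,
                  group = "discount_rate", side = "high"),
    scenario_spec("utility_weights_+20", target = "utility_weights",
                  factor = 1.2, group = "utility_weights", side = "high"),
    scenario_spec("utility_weights_-20", target = "utility_weights",
                  factor = 0.8, group = "utility_weights", side = "low"),
    scenario_spec("glycemic_chd_rr_20", target = "glycemic_macro_rr",
                  value = c(chd = 0.20)),
    scenario_spec("glycemic_stroke_rr_20", target = "glycemic_macro_rr",
                  value = c(stroke = 0.20)),
    scenario_spec("glycemic_chd_stroke_rr_20",
                  structural = "macrovascular_benefit_20pct"),
    scenario_spec("hypertensive_only_screening",
                  structural = "hypertensive_only_screening"),
    scenario_spec("no_intensive_control_comparator",
                  structural = "no_intensive_control_comparator")
  )
}

#' Run one-way sensitivity / scenario analyses
#'
#' Runs the full two-arm pipeline for the base case and for each
#' scenario's perturbed bundle. The shared cohort and life table are
#' built once; every run is deterministic (expected-value cohort). The
#' base bundle is never modified. A scenario whose perturbation is
#' invalid fails individually (with a warning and an `NA` row); other
#' scenarios are unaffected.
#'
#' @param params base `dm_params` bundle
#' @param specs list of `dm_scenario` (default [table4_scenarios()];
#'   an empty list runs the base case only)
#' @param surface,cohort_size,life_table forwarded to [run_cea()]
#' @return a `dm_sa_results` data.frame: `scenario`, `group`, `side`,
#'   `icer`, `delta_cost`, `delta_qaly`, `dominance`, `delta_vs_base`
#' @export
run_scenarios <- function(params, specs = table4_scenarios(),
                          surface = brazil_prevalence_surface(),
                          cohort_size = 1e5,
                          life_table = generate_life_table()) {
  validate_params(params)
  # the cohort is rebuilt per scenario from the scenario's own bundle:
  # the detection-benefit scenarios move the assumed onset time
  run1 <- function(p, comparator_intensive = TRUE) {
    run_cea(p, surface = surface, cohort_size = cohort_size,
            life_table = life_table,
            comparator_intensive = comparator_intensive)
  }
  base <- run1(params)
  rows <- list(data.frame(
    scenario = "base_case", group = NA_character_, side = NA_character_,
    icer = base$ce$icer, delta_cost = base$ce$delta_cost,
    delta_qaly = base$ce$delta_qaly, dominance = base$ce$dominance,
    stringsAsFactors = FALSE))
  for (spec in specs) {
    rows[[length(rows) + 1L]] <- tryCatch({
      sc <- apply_scenario(params, spec)
      res <- run1(sc$params, sc$comparator_intensive)
      data.frame(scenario = spec$name, group = spec$group %||% NA_character_,
                 side = spec$side %||% NA_character_, icer = res$ce$icer,
                 delta_cost = res$ce$delta_cost,
                 delta_qaly = res$ce$delta_qaly,
                 dominance = res$ce$dominance, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("scenario '", spec$name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(scenario = spec$name, group = spec$group %||% NA_character_,
                 side = spec$side %||% NA_character_, icer = NA_real_,
                 delta_cost = NA_real_, delta_qaly = NA_real_,
                 dominance = NA_character_, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out$delta_vs_base <- out$icer - out$icer[1]
  structure(out, class = c("dm_sa_results", "data.frame"))
}

#' Tornado-style ranking of paired sensitivity scenarios
#'
#' Pairs scenarios sharing a `group` with sides `"low"` and `"high"`,
#' computes each pair's ICER spread `|high - low|`, and ranks pairs by
#' spread, descending, ties broken alphabetically by group. Scenarios
#' without a complete pair are skipped with a warning.
#'
#' @param results a `dm_sa_results` from [run_scenarios()]
#' @return data.frame: `group`, `icer_low`, `icer_high`, `spread`,
#'   ordered widest bar first
#' @export
tornado_table <- function(results) {
  g <- results[!is.na(results$group), , drop = FALSE]
  rows <- list()
  for (grp in unique(g$group)) {
    lo <- g$icer[g$group == grp & g$side == "low"]
    hi <- g$icer[g$group == grp & g$side == "high"]
    if (length(lo) != 1 || length(hi) != 1 || is.na(lo) || is.na(hi)) {
      warning("skipping unpaired tornado group '", grp, "'", call. = FALSE)
      next
    }
    rows[[grp]] <- data.frame(group = grp, icer_low = lo, icer_high = hi,
                              spread = abs(hi - lo), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no complete (low, high) scenario pair found")
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$group), ]
  rownames(out) <- NULL
  out
}
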