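#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reporting convention for currency amounts: round to the nearest unit,
#' with ties going away from zero (unlike base [round()], which rounds
#' half to even). Internal accounting always keeps full precision; this
#' is applied at the report layer only.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# ---- parameter bundle ------------------------------------------------------

#' Default economic settings block
#'
#' Fills any settings omitted from a parameter file: 5%/year discount rate,
#' the December 2001 exchange rate (R$ 2.35 per US$), the 2001/2002
#' purchasing-power-parity rate (R$ 0.59 per Int$), currency year 2002,
#' age cap 95, no half-cycle correction.
#'
#' @return named list of settings
#' @export
default_settings <- function() {
  list(
    discount_rate = 0.05,
    brl_per_usd = 2.35,
    brl_per_intl = 0.59,
    currency_year = 2002,
    age_cap = 95,
    half_cycle_correction = FALSE
  )
}

new_dm_params <- function(x) {
  structure(x, class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat("<dm_params> parameter bundle:", x$meta$name %||% "(unnamed)", "\n")
  cat("  transition entries :", nrow(x$transitions), "\n")
  cat("  utility states     :", nrow(x$utilities), "\n")
  cat("  discount rate      :", x$settings$discount_rate, "\n")
  cat("  screening          : sens", x$screening$sensitivity,
      "spec", x$screening$specificity,
      "target", x$screening$target, "\n")
  invisible(x)
}

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- lapply(rec, function(v) if (is.factor(v)) as.character(v) else v)
    # collapse band columns into a [lo, hi] pair for readability on disk
    if (!is.null(rec$band_lo) && !is.na(rec$band_lo)) {
      rec$band <- c(rec$band_lo, rec$band_hi)
    }
    rec$band_lo <- NULL
    rec$band_hi <- NULL
    rec[!vapply(rec, function(v) length(v) == 1 && is.na(v), logical(1))]
  })
}

records_to_df <- function(recs, cols) {
  rows <- lapply(recs, function(rec) {
    if (!is.null(rec$band)) {
      rec$band_lo <- rec$band[[1]]
      rec$band_hi <- rec$band[[2]]
      rec$band <- NULL
    }
    out <- lapply(cols, function(cn) if (is.null(rec[[cn]])) NA else rec[[cn]])
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

params_to_list <- function(bundle) {
  x <- unclass(bundle)
  x$transitions <- df_to_records(bundle$transitions)
  x$stroke_model$table <- if (!is.null(bundle$stroke_model$table)) {
    df_to_records(bundle$stroke_model$table)
  }
  x$costs$complications <- df_to_records(bundle$costs$complications)
  x$costs$standard_glycemic_annual <- df_to_records(bundle$costs$standard_glycemic_annual)
  x$costs$intensified_glycemic_annual <- df_to_records(bundle$costs$intensified_glycemic_annual)
  x$utilities <- df_to_records(bundle$utilities)
  # named vectors go to disk as maps (yaml drops atomic-vector names)
  x$treatment_effects <- lapply(bundle$treatment_effects, as.list)
  if (!is.null(bundle$stroke_model$coef)) {
    x$stroke_model$coef <- as.list(bundle$stroke_model$coef)
  }
  x
}

params_from_list <- function(x) {
  x$transitions <- records_to_df(
    x$transitions, c("from", "to", "stratum", "band_lo", "band_hi", "prob"))
  if (!is.null(x$stroke_model$table)) {
    x$stroke_model$table <- records_to_df(
      x$stroke_model$table, c("sex", "hypertensive", "age_lo", "age_hi", "prob"))
  }
  x$costs$complications <- records_to_df(
    x$costs$complications, c("item", "type", "usd"))
  x$costs$standard_glycemic_annual <- records_to_df(
    x$costs$standard_glycemic_annual, c("band_lo", "band_hi", "usd"))
  x$costs$intensified_glycemic_annual <- records_to_df(
    x$costs$intensified_glycemic_annual, c("band_lo", "band_hi", "usd"))
  x$utilities <- records_to_df(x$utilities, c("state", "utility"))
  x$settings <- utils::modifyList(default_settings(), x$settings %||% list())
  x$treatment_effects <- lapply(x$treatment_effects, function(v) unlist(v))
  if (!is.null(x$stroke_model$coef)) {
    x$stroke_model$coef <- unlist(x$stroke_model$coef)
  }
  new_dm_params(x)
}

#' Load a model parameter bundle from file
#'
#' Reads a parameter file (YAML canonical, JSON accepted, selected by file
#' extension), fills defaulted blocks, validates every invariant and
#' returns the bundle. The bundled Brazil 2001 base case is available via
#' [brazil_params()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` parameter file
#' @return a validated `dm_params` bundle
#' @seealso [save_params()], [validate_params()], [perturb_params()]
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    stop("unsupported parameter file extension: .", ext,
         " (expected .yaml, .yml or .json)"))
  bundle <- params_from_list(raw)
  validate_params(bundle)
  bundle
}

#' Save a parameter bundle to file
#'
#' Inverse of [load_params()]; format chosen by extension. A
#' save-then-load round trip reproduces the bundle.
#'
#' @param bundle a `dm_params` bundle
#' @param path destination path (`.yaml`, `.yml` or `.json`)
#' @return `path`, invisibly
#' @export
save_params <- function(bundle, path) {
  x <- params_to_list(bundle)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    stop("unsupported parameter file extension: .", ext))
  invisible(path)
}

#' The Brazil 2001 base-case parameter bundle
#'
#' Loads the packaged fixture encoding the base-case inputs of the 2001
#' Brazilian nationwide diabetes screening program analysis: annual
#' health-state transition probabilities, screening test characteristics
#' (sensitivity 68%, specificity 89%), complication costs in 2001 US$,
#' treatment cost assumptions, utility weights, and economic settings.
#' Utility weights, the Weibull coronary heart disease parameters, the
#' stroke risk table, treatment cost levels and acute coronary event
#' splits are documented modelling assumptions (marked in the fixture);
#' the remaining values are the published program inputs.
#'
#' @return a validated `dm_params` bundle
#' @export
brazil_params <- function() {
  load_params(system.file("extdata", "brazil_2001.yaml",
                          package = "dmscreen", mustWork = TRUE))
}

# ---- validation ------------------------------------------------------------

chk <- function(ok, key, msg) {
  if (!all(ok)) stop("invalid parameter '", key, "': ", msg, call. = FALSE)
}

in01 <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

#' Validate a parameter bundle
#'
#' Checks every declared invariant: probabilities, fractions and utility
#' weights in \[0, 1\] (death exactly 0), non-negative costs, positive
#' Weibull shape/scale, contiguous non-overlapping year bands covering
#' 0 to 94 years, explicit exit probabilities summing to at most 1 per
#' origin state and stratum, and the screening policy constraint
#' `0 < detection_benefit_years <= lead_time_years`. Errors name the
#' offending key and constraint.
#'
#' @param bundle a `dm_params` bundle
#' @return `TRUE` invisibly if valid, otherwise an error
#' @export
validate_params <- function(bundle) {
  tr <- bundle$transitions
  chk(all(c("from", "to", "stratum", "prob") %in% names(tr)),
      "transitions", "missing required column")
  chk(in01(tr$prob), "transitions.prob", "must be in [0, 1]")

  # year bands: contiguous, non-overlapping, covering [0, 94]
  banded <- tr[!is.na(tr$band_lo), , drop = FALSE]
  if (nrow(banded)) {
    for (key in unique(paste(banded$from, banded$to, banded$stratum))) {
      g <- banded[paste(banded$from, banded$to, banded$stratum) == key, ]
      g <- g[order(g$band_lo), ]
      chk(g$band_lo[1] == 0 && g$band_hi[nrow(g)] == 94,
          paste0("transitions[", key, "].band"), "bands must cover [0, 94]")
      if (nrow(g) > 1) {
        chk(all(g$band_lo[-1] == g$band_hi[-nrow(g)] + 1),
            paste0("transitions[", key, "].band"),
            "bands must be contiguous and non-overlapping")
      }
    }
  }

  # explicit exits never exceed total mass (residual stays in from-state)
  for (st in unique(tr$stratum)) {
    for (fr in unique(tr$from[tr$stratum == st])) {
      for (yr in c(0, 5, 8, 12, 13, 19, 20, 94)) {
        tot <- sum(vapply(
          unique(tr$to[tr$from == fr & tr$stratum == st]),
          function(to) transition_prob(bundle, fr, to, st, yr),
          numeric(1)))
        chk(tot <= 1 + 1e-12, paste0("transitions[", fr, ", ", st, "]"),
            "sum of exit probabilities exceeds 1")
      }
    }
  }

  cm <- bundle$chd_model
  chk(is.numeric(cm$shape) && cm$shape > 0, "chd_model.shape", "must be > 0")
  chk(is.numeric(cm$scale) && cm$scale > 0, "chd_model.scale", "must be > 0")
  chk(in01(cm$mi_fraction), "chd_model.mi_fraction", "must be in [0, 1]")
  chk(in01(cm$mi_case_fatality), "chd_model.mi_case_fatality", "must be in [0, 1]")
  chk(in01(cm$mi_death_no_hosp_share), "chd_model.mi_death_no_hosp_share",
      "must be in [0, 1]")

  sm <- bundle$stroke_model
  chk(sm$mode %in% c("table", "equation"), "stroke_model.mode",
      "must be 'table' or 'equation'")
  if (sm$mode == "table") {
    chk(!is.null(sm$table), "stroke_model.table", "required in table mode")
    chk(in01(sm$table$prob), "stroke_model.table.prob", "must be in [0, 1]")
  } else {
    chk(is.numeric(sm$coef) && !is.null(names(sm$coef)), "stroke_model.coef",
        "named numeric coefficient vector required in equation mode")
  }

  te <- bundle$treatment_effects
  chk(all(te$glycemic_micro > 0 & te$glycemic_micro <= 1),
      "treatment_effects.glycemic_micro", "hazard multipliers must be in (0, 1]")
  chk(all(te$glycemic_macro_rr >= 0 & te$glycemic_macro_rr < 1),
      "treatment_effects.glycemic_macro_rr", "risk reductions must be in [0, 1)")
  chk(all(te$hypertension_rr >= 0 & te$hypertension_rr < 1),
      "treatment_effects.hypertension_rr", "risk reductions must be in [0, 1)")

  sc <- bundle$screening
  for (f in c("sensitivity", "specificity", "fasting_fraction")) {
    chk(in01(sc[[f]]), paste0("screening.", f), "must be in [0, 1]")
  }
  for (f in c("cost_per_screen", "cost_per_confirmation")) {
    chk(is.numeric(sc[[f]]) && sc[[f]] >= 0, paste0("screening.", f),
        "must be >= 0")
  }
  # 0 is admitted as the degenerate no-benefit policy (lead-time
  # neutrality checks); a useful program has benefit > 0
  chk(sc$detection_benefit_years >= 0 &&
        sc$detection_benefit_years <= sc$lead_time_years,
      "screening.detection_benefit_years",
      "must satisfy 0 <= detection_benefit_years <= lead_time_years")
  chk(sc$target %in% c("all_40plus", "hypertensive_only"), "screening.target",
      "must be 'all_40plus' or 'hypertensive_only'")

  co <- bundle$costs
  chk(all(co$complications$usd >= 0), "costs.complications.usd", "must be >= 0")
  chk(all(co$standard_glycemic_annual$usd >= 0),
      "costs.standard_glycemic_annual.usd", "must be >= 0")
  chk(all(co$intensified_glycemic_annual$usd >= 0),
      "costs.intensified_glycemic_annual.usd", "must be >= 0")
  chk(co$intensified_hypertension_annual >= 0,
      "costs.intensified_hypertension_annual", "must be >= 0")
  chk(co$background_care_annual >= 0, "costs.background_care_annual",
      "must be >= 0")
  chk(co$cost_of_death >= 0, "costs.cost_of_death", "must be >= 0")

  ut <- bundle$utilities
  chk(in01(ut$utility), "utilities.utility", "must be in [0, 1]")
  chk("death" %in% ut$state, "utilities", "must include state 'death'")
  chk(ut$utility[ut$state == "death"] == 0, "utilities[death]",
      "death utility must be exactly 0")
  chk("no_complication" %in% ut$state, "utilities",
      "must include state 'no_complication'")
  u0 <- ut$utility[ut$state == "no_complication"]
  chk(all(ut$utility <= u0 + 1e-12), "utilities",
      "no state may exceed the no-complication baseline")

  se <- bundle$settings
  chk(is.numeric(se$discount_rate) && se$discount_rate >= 0,
      "settings.discount_rate", "must be >= 0")
  chk(se$brl_per_usd > 0, "settings.brl_per_usd", "must be > 0")
  chk(se$brl_per_intl > 0, "settings.brl_per_intl", "must be > 0")

  invisible(TRUE)
}

# ---- lookup ----------------------------------------------------------------

#' Look up an annual transition probability
#'
#' Resolves a Table-of-transition-probabilities entry for a move
#' `from -> to` in a given hypertension-control stratum and, where the
#' table stratifies by duration, the years-since-diagnosis band. Bands
#' are half-open on integer completed years: band \[lo, hi\] covers
#' completed years `lo` through `hi` inclusive. Returns 0 when no entry
#' exists for the pair (no explicit exit).
#'
#' @param bundle a `dm_params` bundle
#' @param from,to health-state labels as used in the transition table
#' @param stratum `"baseline"`, `"moderate"`, `"tight"`, or a
#'   case-fatality label; entries recorded with stratum `"all"` match any
#' @param years_since_dx completed years since diabetes diagnosis
#'   (used only for duration-banded entries)
#' @return annual probability in \[0, 1\]
#' @export
transition_prob <- function(bundle, from, to, stratum = "baseline",
                            years_since_dx = 0) {
  tr <- bundle$transitions
  hit <- tr$from == from & tr$to == to &
    (tr$stratum == stratum | tr$stratum == "all")
  g <- tr[hit, , drop = FALSE]
  if (!nrow(g)) return(0)
  if (all(is.na(g$band_lo))) {
    if (nrow(g) > 1) g <- g[g$stratum == stratum, , drop = FALSE]
    return(g$prob[1])
  }
  yr <- max(0, years_since_dx)
  row <- g[!is.na(g$band_lo) & g$band_lo <= yr & g$band_hi >= yr, , drop = FALSE]
  if (!nrow(row)) {
    stop("no transition entry for ", from, " -> ", to, " at ", yr,
         " years since diagnosis")
  }
  row$prob[1]
}

# ---- perturbation ----------------------------------------------------------

.perturb_groups <- c(
  "screening_costs", "glycemic_treatment_costs",
  "hypertension_treatment_costs", "complication_costs", "utility_weights",
  "detection_benefit_years", "discount_rate", "glycemic_macro_rr",
  "screening_target"
)

#' Perturb a parameter group for sensitivity analysis
#'
#' Returns a deep copy of the bundle with exactly one named parameter
#' group changed, either multiplied by `factor` (the +/-20% style rows of
#' a one-way sensitivity analysis) or replaced by `value`. The input
#' bundle is never modified. Valid groups:
#' `r paste0('\x60', .perturb_groups, '\x60', collapse = ", ")`.
#'
#' Multiplicative groups scale every cost (or every non-death utility
#' weight) in the group; replacement groups (`detection_benefit_years`,
#' `discount_rate`, `glycemic_macro_rr`, `screening_target`) take `value`.
#' The perturbed bundle is re-validated before return.
#'
#' @param bundle a `dm_params` bundle
#' @param target name of the parameter group to change
#' @param factor positive multiplicative factor (exclusive with `value`)
#' @param value replacement value (exclusive with `factor`)
#' @return a new validated `dm_params` bundle
#' @export
perturb_params <- function(bundle, target, factor = NULL, value = NULL) {
  if (!target %in% .perturb_groups) {
    stop("unknown parameter group '", target, "'; valid groups: ",
         paste(.perturb_groups, collapse = ", "))
  }
  if (is.null(factor) == is.null(value)) {
    stop("supply exactly one of 'factor' or 'value'")
  }
  if (!is.null(factor) && factor <= 0) stop("'factor' must be > 0")
  out <- bundle
  f <- factor %||% 1
  switch(target,
    screening_costs = {
      if (!is.null(value)) stop("screening_costs is multiplicative; use 'factor'")
      out$screening$cost_per_screen <- out$screening$cost_per_screen * f
      out$screening$cost_per_confirmation <- out$screening$cost_per_confirmation * f
    },
    glycemic_treatment_costs = {
      out$costs$intensified_glycemic_annual$usd <-
        out$costs$intensified_glycemic_annual$usd * f
    },
    hypertension_treatment_costs = {
      out$costs$intensified_hypertension_annual <-
        out$costs$intensified_hypertension_annual * f
    },
    complication_costs = {
      out$costs$complications$usd <- out$costs$complications$usd * f
    },
    utility_weights = {
      keep <- out$utilities$state != "death"
      out$utilities$utility[keep] <- out$utilities$utility[keep] * f
    },
    detection_benefit_years = {
      if (is.null(value)) stop("detection_benefit_years takes 'value'")
      out$screening$detection_benefit_years <- value
    },
    discount_rate = {
      if (is.null(value)) stop("discount_rate takes 'value'")
      out$settings$discount_rate <- value
    },
    glycemic_macro_rr = {
      if (is.null(value)) stop("glycemic_macro_rr takes 'value'")
      if (is.null(names(value))) value <- c(chd = value[1], stroke = value[1])
      out$treatment_effects$glycemic_macro_rr <-
        utils::modifyList(as.list(out$treatment_effects$glycemic_macro_rr),
                          as.list(value)) |> unlist()
    },
    screening_target = {
      if (is.null(value)) stop("screening_target takes 'value'")
      out$screening$target <- value
    }
  )
  validate_params(out)
  out
}
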