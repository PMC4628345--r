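# Discounted cost and QALY accrual, ICER computation and currency
# conversion. All internal accounting is in 2002-adjusted US$; the
# international-dollar conversion happens only in convert_currency().

#' Discount factor
#'
#' `(1 + rate)^(-year)`; year 0 is undiscounted.
#'
#' @param year integer year (>= 0); vectorized
#' @param rate annual discount rate (>= 0)
#' @return discount factor(s)
#' @export
discount_factor <- function(year, rate) {
  if (any(year < 0)) stop("year must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-year)
}

cost_item <- function(costs, item, type) {
  cc <- costs$complications
  hit <- cc$item == item & cc$type == type
  if (!any(hit)) stop("no cost entry for ", item, " (", type, ")")
  cc$usd[which(hit)[1]]
}

band_vector <- function(df, max_year = 94) {
  v <- numeric(max_year + 1)
  for (i in seq_len(nrow(df))) {
    v[(df$band_lo[i]:min(df$band_hi[i], max_year)) + 1] <- df$usd[i]
  }
  v
}

utility_of <- function(utilities, state) {
  hit <- utilities$state == state
  if (!any(hit)) stop("no utility entry for state '", state, "'")
  utilities$utility[which(hit)[1]]
}

#' Accrue discounted costs, QALYs and life-years over a trajectory
#'
#' Charges, per cycle: annual complication costs on end-of-cycle
#' occupancy (end-stage renal disease, angina, CA/MI history,
#' post-stroke care), one-time complication costs on event masses,
#' standard diabetes treatment from diagnosis, incremental intensified
#' glycemic (by years since diagnosis) and hypertension control while on
#' intensified treatment, background medical care for everyone alive,
#' and the cost of death once at death. QALYs accrue as occupancy times
#' the state utility: the no-complication diabetes baseline minus
#' additive complication decrements (the standard additive-decrement
#' combination for comorbid states). All streams are discounted to
#' cycle 0; the one-time screening/confirmation cost enters undiscounted
#' at cycle 0.
#'
#' @param trajectory a `dm_trajectory` from [simulate_lifetime()]
#' @param costs cost table block (`params$costs`)
#' @param utilities utility table (`params$utilities`)
#' @param settings economic settings (`params$settings`)
#' @param screening_cost one-time screening + confirmation cost charged
#'   at cycle 0 (default 0)
#' @param label arm label for reporting
#' @return a `dm_ledger`: list with `by_cycle` (discounted per-cycle
#'   costs by category, QALYs, life-years), `totals`, `n_cases`,
#'   `discount_rate`, `label`
#' @export
accrue <- function(trajectory, costs, utilities, settings,
                   screening_cost = 0, label = attr(trajectory, "arm")) {
  tr <- trajectory
  r <- settings$discount_rate
  if (!nrow(tr)) {
    cats <- c("treatment", "complications", "screening",
              "intensified_control", "background_care", "death")
    by_cycle <- as.data.frame(c(
      list(cycle = 0), as.list(stats::setNames(rep(0, 6), cats)),
      list(qaly = 0, ly = 0, cost_total = screening_cost)))
    by_cycle$screening <- screening_cost
    totals <- as.list(colSums(by_cycle[c(cats, "cost_total", "qaly", "ly")]))
    return(structure(list(by_cycle = by_cycle, totals = totals,
                          n_cases = attr(trajectory, "n_cases") %||% 0,
                          discount_rate = r, label = label),
                     class = "dm_ledger"))
  }
  df <- discount_factor(tr$cycle, r)

  c_ann <- tr$occ_esrd * cost_item(costs, "esrd", "annual") +
    tr$occ_angina * cost_item(costs, "angina", "annual") +
    tr$occ_history_ca_mi * cost_item(costs, "history_ca_mi", "annual") +
    (tr$occ_stroke_year1 + tr$occ_stroke_history) *
      cost_item(costs, "stroke", "annual")
  c_one <- tr$ev_nephropathy * cost_item(costs, "nephropathy", "one_time") +
    tr$ev_pn * cost_item(costs, "peripheral_neuropathy", "one_time") +
    tr$ev_lea * cost_item(costs, "lea", "one_time") +
    tr$ev_photo * cost_item(costs, "photocoagulation", "one_time") +
    tr$ev_angina * cost_item(costs, "angina", "one_time") +
    tr$ev_mi_surv * cost_item(costs, "mi_survivor", "one_time") +
    tr$ev_mi_death_nohosp * cost_item(costs, "mi_death_no_hosp", "one_time") +
    tr$ev_mi_death_hosp * cost_item(costs, "mi_death_hosp", "one_time") +
    tr$ev_stroke_surv * cost_item(costs, "stroke", "one_time") +
    tr$ev_stroke_death_imm *
      cost_item(costs, "stroke_immediate_death", "one_time")
  complications <- (c_ann + c_one) * df

  treated_alive <- tr$alive * tr$treated
  std <- band_vector(costs$standard_glycemic_annual)
  igly <- band_vector(costs$intensified_glycemic_annual)
  ysd_idx <- pmin(tr$ysd, 94) + 1
  treatment <- treated_alive * std[ysd_idx] * df
  intensified <- if (isTRUE(attr(trajectory, "intensive"))) {
    treated_alive *
      (igly[ysd_idx] + tr$ht * costs$intensified_hypertension_annual) * df
  } else {
    numeric(nrow(tr))
  }
  background <- tr$alive * costs$background_care_annual * df
  death <- tr$d_total * costs$cost_of_death * df

  u0 <- utility_of(utilities, "no_complication")
  dec <- function(state) u0 - utility_of(utilities, state)
  qaly_raw <- tr$alive * u0 -
    tr$occ_microalbuminuria * dec("microalbuminuria") -
    tr$occ_nephropathy * dec("nephropathy") -
    tr$occ_esrd * dec("esrd") -
    tr$occ_peripheral_neuropathy * dec("peripheral_neuropathy") -
    tr$occ_lea * dec("lea") -
    tr$occ_photocoagulation * dec("photocoagulation") -
    tr$occ_blindness * dec("blindness") -
    tr$occ_angina * dec("angina") -
    tr$occ_history_ca_mi * dec("history_ca_mi") -
    (tr$occ_stroke_year1 + tr$occ_stroke_history) * dec("stroke")
  qaly <- qaly_raw * df
  ly <- tr$alive * df

  agg <- function(x) as.numeric(tapply(x, tr$cycle, sum))
  cycles <- sort(unique(tr$cycle))
  by_cycle <- data.frame(
    cycle = cycles,
    treatment = agg(treatment),
    complications = agg(complications),
    screening = ifelse(cycles == 0, screening_cost, 0),
    intensified_control = agg(intensified),
    background_care = agg(background),
    death = agg(death),
    qaly = agg(qaly),
    ly = agg(ly)
  )
  cats <- c("treatment", "complications", "screening", "intensified_control",
            "background_care", "death")
  by_cycle$cost_total <- rowSums(by_cycle[cats])
  totals <- c(as.list(colSums(by_cycle[c(cats, "cost_total", "qaly", "ly")])))
  structure(list(by_cycle = by_cycle, totals = totals,
                 n_cases = attr(trajectory, "n_cases"),
                 discount_rate = r, label = label),
            class = "dm_ledger")
}

#' @export
print.dm_ledger <- function(x, ...) {
  cat("<dm_ledger>", x$label %||% "", "| discount", x$discount_rate, "\n")
  pc <- unlist(x$totals) / x$n_cases
  cat("  per case: cost", sprintf("%.2f US$", pc[["cost_total"]]),
      "| QALYs", sprintf("%.4f", pc[["qaly"]]),
      "| LYs", sprintf("%.4f", pc[["ly"]]), "\n")
  invisible(x)
}

#' Incremental cost-effectiveness from cost and QALY deltas
#'
#' The ICER is `delta_cost / delta_qaly` (US$ per QALY gained), defined
#' only when the strategy is neither dominant (cheaper and more
#' effective) nor dominated (costlier and less effective) and the QALY
#' delta is nonzero. `icer_reported` rounds half-away-from-zero to the
#' nearest dollar; full precision is retained in `icer`.
#'
#' @param delta_cost incremental cost (US$)
#' @param delta_qaly incremental QALYs
#' @param delta_ly incremental life-years (optional, reporting only)
#' @return a `dm_ce_result`: `delta_cost`, `delta_qaly`, `delta_ly`,
#'   `icer`, `icer_reported`, `dominance`
#'   (`"none"`, `"dominant"`, `"dominated"`, `"undefined"`)
#' @export
icer <- function(delta_cost, delta_qaly, delta_ly = NA_real_) {
  dominance <- if (delta_qaly == 0) {
    if (delta_cost == 0) "none" else "undefined"
  } else if (delta_qaly > 0 && delta_cost < 0) {
    "dominant"
  } else if (delta_qaly < 0 && delta_cost > 0) {
    "dominated"
  } else {
    "none"
  }
  val <- if (dominance == "none" && delta_qaly != 0) {
    delta_cost / delta_qaly
  } else if (dominance == "none") {
    0
  } else if (dominance == "dominant") {
    delta_cost / delta_qaly  # negative; reported alongside the flag
  } else {
    NA_real_
  }
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 delta_ly = delta_ly, icer = val,
                 icer_reported = if (is.na(val)) NA_real_ else round_half_away(val),
                 dominance = dominance),
            class = "dm_ce_result")
}

#' Incremental cost-effectiveness of screening vs no screening
#'
#' Per-true-case deltas between the two arms' ledgers (both arms follow
#' the same undiagnosed cases, so the normalizing mass is identical).
#'
#' @param ledger_screened,ledger_unscreened `dm_ledger` objects
#' @return a `dm_ce_result` (see [icer()])
#' @export
compute_icer <- function(ledger_screened, ledger_unscreened) {
  s <- ledger_screened
  u <- ledger_unscreened
  if (abs(s$n_cases - u$n_cases) > 1e-6 * max(s$n_cases, 1)) {
    stop("arm ledgers cover different case masses")
  }
  n <- s$n_cases
  icer((s$totals$cost_total - u$totals$cost_total) / n,
       (s$totals$qaly - u$totals$qaly) / n,
       (s$totals$ly - u$totals$ly) / n)
}

#' @export
print.dm_ce_result <- function(x, ...) {
  cat("<dm_ce_result>\n")
  cat(sprintf("  incremental cost  : %+.2f US$/case\n", x$delta_cost))
  cat(sprintf("  incremental QALYs : %+.5f /case\n", x$delta_qaly))
  if (!is.na(x$delta_ly)) {
    cat(sprintf("  incremental LYs   : %+.5f /case\n", x$delta_ly))
  }
  if (x$dominance == "none") {
    cat(sprintf("  ICER              : %s US$/QALY\n",
                format(x$icer_reported, big.mark = ",")))
  } else {
    cat("  dominance         :", x$dominance, "\n")
  }
  invisible(x)
}

#' Convert US$ amounts to international dollars
#'
#' Routes through the local currency at the market exchange rate and out
#' at the purchasing-power-parity rate:
#' `amount_intl = amount_usd * brl_per_usd / brl_per_intl`.
#' Rounding is left to the report layer.
#'
#' @param amount_usd amount in US$; vectorized
#' @param settings economic settings with `brl_per_usd` and
#'   `brl_per_intl`
#' @return amount in Int$
#' @export
convert_currency <- function(amount_usd, settings) {
  stopifnot(settings$brl_per_usd > 0, settings$brl_per_intl > 0)
  amount_usd * settings$brl_per_usd / settings$brl_per_intl
}

#' Arm-by-arm cost-effectiveness summary table
#'
#' A three-row summary (no screening, screening, incremental) of
#' per-true-case discounted costs by category, life-years, QALYs, and
#' the ICER on the incremental row.
#'
#' @param ledger_screened,ledger_unscreened `dm_ledger` objects
#' @return data.frame
#' @export
ce_summary <- function(ledger_screened, ledger_unscreened) {
  per_case <- function(l) unlist(l$totals) / l$n_cases
  s <- per_case(ledger_screened)
  u <- per_case(ledger_unscreened)
  d <- s - u
  res <- compute_icer(ledger_screened, ledger_unscreened)
  cols <- c("treatment", "complications", "screening", "intensified_control",
            "background_care", "death", "cost_total", "ly", "qaly")
  out <- rbind(as.data.frame(as.list(u[cols])),
               as.data.frame(as.list(s[cols])),
               as.data.frame(as.list(d[cols])))
  out$strategy <- c("no_screening", "screening", "incremental")
  out$icer_usd_per_qaly <- c(NA, NA, res$icer_reported)
  out[c("strategy", cols, "icer_usd_per_qaly")]
}
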