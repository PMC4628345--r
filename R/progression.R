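# The Markov engine: annual-cycle evolution of a diabetes cohort through
# renal, neuropathy, retinal, coronary heart disease (CHD) and stroke
# complication tracks plus cause-tagged death.
#
# State representation: tracks advance independently within a cycle and
# every cross-track coupling acts through stratum-level covariates or
# through survival factors that multiply across tracks. Occupancy is
# therefore stored as an alive mass together with one conditional
# distribution per track (renal 4 states, neuropathy 3, retinal 3,
# CHD 3, stroke 3); the joint compound-state occupancy is their product.
# This factorization is exact for the model structure used here and is
# cross-checked against an individual-level Monte Carlo simulation in the
# test suite.

.renal_states <- c("renal_normal", "microalbuminuria", "nephropathy", "esrd")
.neuro_states <- c("neuro_normal", "peripheral_neuropathy", "lea")
.retina_states <- c("retina_normal", "photocoagulation", "blindness")
.chd_states <- c("chd_none", "angina", "history_ca_mi")
.stroke_states <- c("stroke_none", "stroke_year1", "stroke_history")

#' Create a cohort occupancy state
#'
#' An occupancy state holds the alive mass and, per complication track,
#' the conditional distribution over that track's states. A fresh state
#' has all mass complication-free.
#'
#' @param mass alive mass (>= 0)
#' @return a `dm_state` list with elements `alive`, `renal`, `neuro`,
#'   `retina`, `chd`, `stroke`
#' @export
dm_state <- function(mass = 1) {
  structure(list(
    alive = mass,
    renal = c(1, 0, 0, 0),
    neuro = c(1, 0, 0),
    retina = c(1, 0, 0),
    chd = c(1, 0, 0),
    stroke = c(1, 0, 0)
  ), class = "dm_state")
}

#' Discrete annual CHD incidence from a Weibull onset-time model
#'
#' The probability of a first coronary heart disease event in year `t`
#' since diabetes onset, given event-free survival to `t - 1`:
#' `CHD(t) = (F(t) - F(t-1)) / (1 - F(t-1))` with `F` the Weibull
#' cumulative distribution over time since onset.
#'
#' @param t integer years since onset (>= 1); vectorized
#' @param model list with positive `shape` and `scale` (years)
#' @return annual probability in \[0, 1\]
#' @export
chd_incidence <- function(t, model) {
  if (any(t < 1)) stop("t must be >= 1 (years since diabetes onset)")
  Ft <- stats::pweibull(t, shape = model$shape, scale = model$scale)
  Fp <- stats::pweibull(t - 1, shape = model$shape, scale = model$scale)
  if (any(Fp >= 1)) stop("Weibull support exhausted: F(t - 1) = 1")
  (Ft - Fp) / (1 - Fp)
}

#' Convert a multi-year risk to an annual probability
#'
#' Constant-hazard conversion `p = 1 - (1 - R)^(1/horizon)`.
#'
#' @param R cumulative risk over `horizon` years, in \[0, 1)
#' @param horizon risk horizon in years (default 10)
#' @return annual probability
#' @export
annualize_risk <- function(R, horizon = 10) {
  stopifnot(all(R >= 0 & R < 1))
  1 - (1 - R)^(1 / horizon)
}

#' Annual first-stroke probability
#'
#' In `"table"` mode, an exact lookup of the annual probability by age
#' band, sex and hypertension status. In `"equation"` mode, a
#' Framingham-type 10-year risk function
#' `R10 = 1 - s0 ^ exp(lp)` with linear predictor
#' `lp = b_age * (age - 50) + b_male * male + b_hypertension * ht +
#' b_smoking * smk + b_hchol * hchol` (`s0` the baseline 10-year
#' stroke-free survival), converted to an annual probability with
#' [annualize_risk()]. With all coefficients zero the equation returns
#' the baseline-survival-implied probability only. Fractional smoking /
#' hypercholesterolemia covariates are handled by exact mixture over the
#' binary combinations, so stratum-level expected values are exact.
#'
#' @param context list with `age`, `sex`, `hypertensive` and, for
#'   equation mode, `p_smoking` and `p_hchol` (fractions or 0/1)
#' @param model a stroke risk model (`mode`, plus `table` or `coef`)
#' @return annual probability in \[0, 1\]
#' @export
stroke_incidence <- function(context, model) {
  if (model$mode == "table") {
    tb <- model$table
    hit <- tb$sex == context$sex & tb$hypertensive == context$hypertensive &
      tb$age_lo <= context$age & tb$age_hi >= context$age
    if (!any(hit)) {
      stop("no stroke table entry for age ", context$age, ", sex ",
           context$sex, ", hypertensive ", context$hypertensive)
    }
    return(tb$prob[which(hit)[1]])
  }
  cf <- model$coef
  need <- c("s0", "age", "male", "hypertension", "smoking", "hchol")
  if (!all(need %in% names(cf))) {
    stop("stroke equation coefficients missing: ",
         paste(setdiff(need, names(cf)), collapse = ", "))
  }
  for (v in c("age", "sex", "hypertensive")) {
    if (is.null(context[[v]])) stop("stroke equation covariate missing: ", v)
  }
  psm <- context$p_smoking %||% 0
  phc <- context$p_hchol %||% 0
  base_lp <- cf[["age"]] * (context$age - 50) +
    cf[["male"]] * (context$sex == "male") +
    cf[["hypertension"]] * isTRUE(context$hypertensive)
  p <- 0
  for (smk in 0:1) {
    for (hc in 0:1) {
      w <- (if (smk) psm else 1 - psm) * (if (hc) phc else 1 - phc)
      if (w == 0) next
      lp <- base_lp + cf[["smoking"]] * smk + cf[["hchol"]] * hc
      p <- p + w * annualize_risk(1 - cf[["s0"]]^exp(lp))
    }
  }
  p
}

#' Apply treatment effects to baseline transition probabilities
#'
#' Intensified glycemic control multiplies the microvascular hazards
#' (microalbuminuria, nephropathy, peripheral neuropathy,
#' photocoagulation pathways) by the configured hazard multipliers, and
#' in the macrovascular-benefit scenario additionally reduces CHD and
#' stroke probabilities by the configured relative risk reduction (zero
#' in the base case). Intensified hypertension control reduces stroke
#' and CHD probabilities by the configured relative risk reductions.
#' Effects apply only to diagnosed (treated) persons; hypertension
#' effects additionally require the person to be hypertensive.
#'
#' @param base named probability vector; recognized names:
#'   `microalbuminuria`, `nephropathy`, `neuropathy`, `photocoagulation`,
#'   `chd`, `stroke`
#' @param context list with logicals `treated`, `intensive` (intensified
#'   control available in this arm) and `hypertensive`
#' @param effects a `treatment_effects` block (see [brazil_params()])
#' @return adjusted named probability vector
#' @export
apply_treatment_effects <- function(base, context, effects) {
  out <- base
  if (isTRUE(context$treated) && isTRUE(context$intensive)) {
    gm <- effects$glycemic_micro
    map <- c(microalbuminuria = "microalbuminuria", nephropathy = "nephropathy",
             neuropathy = "neuropathy", photocoagulation = "photocoagulation")
    for (nm in intersect(names(out), names(map))) {
      out[nm] <- out[nm] * gm[[map[[nm]]]]
    }
    for (nm in intersect(names(out), c("chd", "stroke"))) {
      out[nm] <- out[nm] * (1 - effects$glycemic_macro_rr[[nm]])
      if (isTRUE(context$hypertensive)) {
        out[nm] <- out[nm] * (1 - effects$hypertension_rr[[nm]])
      }
    }
  }
  if (any(out < 0 | out > 1)) {
    stop("adjusted probability outside [0, 1]: ",
         paste(names(out)[out < 0 | out > 1], collapse = ", "))
  }
  out
}

# ---- compiled tables -------------------------------------------------------

# Pre-resolve every probability lookup into flat vectors so the cycle
# kernel is plain arithmetic. Year-band probabilities are indexed by
# completed years since diagnosis 0..94; CHD(t) by years since onset.
compile_tables <- function(params, max_onset_years = 130) {
  tp <- function(...) transition_prob(params, ...)
  strata <- c("baseline", "moderate", "tight")
  yrs <- 0:94
  chd_t <- seq_len(max_onset_years)
  Ft <- stats::pweibull(chd_t, params$chd_model$shape, params$chd_model$scale)
  Fp <- stats::pweibull(chd_t - 1, params$chd_model$shape, params$chd_model$scale)
  list(
    p_micro = vapply(strata, function(s) tp("renal_normal", "microalbuminuria", s), 1),
    p_neph = vapply(strata, function(s) tp("microalbuminuria", "nephropathy", s), 1),
    p_esrd = vapply(yrs, function(y) tp("nephropathy", "esrd", "all", y), 1),
    p_pn = tp("neuro_normal", "peripheral_neuropathy", "all"),
    p_lea = vapply(yrs, function(y) tp("peripheral_neuropathy", "lea", "all", y), 1),
    p_photo = vapply(strata, function(s) tp("retina_normal", "photocoagulation", s), 1),
    p_blind = vapply(strata, function(s) tp("photocoagulation", "blindness", s), 1),
    cf_stroke_imm = tp("stroke_event", "death", "immediate"),
    cf_stroke_yr1 = tp("stroke_event", "death", "year1"),
    p_esrd_death = tp("esrd", "death", "all"),
    chd_p = pmin((Ft - Fp) / pmax(1 - Fp, 1e-300), 1),
    stroke_model = params$stroke_model,
    effects = params$treatment_effects,
    mi_fraction = params$chd_model$mi_fraction,
    mi_cf = params$chd_model$mi_case_fatality,
    mi_nh_share = params$chd_model$mi_death_no_hosp_share
  )
}

ctx_stratum <- function(context) {
  if (!isTRUE(context$hypertensive)) {
    "baseline"
  } else if (isTRUE(context$treated) && isTRUE(context$intensive)) {
    "tight"
  } else {
    "moderate"
  }
}

#' Background mortality and acute events for one cycle
#'
#' Applies, in order: background all-cause mortality to every alive
#' state; the extra first-year post-stroke mortality to last cycle's
#' stroke survivors (who then join the post-stroke history state); new
#' stroke events with immediate case fatality (survivors enter the
#' first-year state); new CHD events split into angina and cardiac
#' arrest / myocardial infarction (CA/MI), with MI case fatality split
#' into death without hospitalization and death within 30 days; and the
#' excess mortality of end-stage renal disease, if the transition table
#' carries an `esrd -> death` entry. Mass is conserved exactly:
#' `alive + deaths` is unchanged.
#'
#' @param state a `dm_state`
#' @param context list with `age`, `sex`, `hypertensive`, `treated`,
#'   `intensive`, `t_onset` (years since onset, >= 1), `p_smoking`,
#'   `p_hchol`
#' @param life_table a `dm_life_table` (or `NULL` to skip background
#'   mortality, as during pre-screening burn-in where survival is
#'   conditioned away)
#' @param tables compiled tables from a parameter bundle (internally
#'   produced; pass a `dm_params` bundle and it is compiled on the fly)
#' @return list with `state` (next state), `deaths` (named masses:
#'   `background`, `stroke`, `chd`, `total`) and `events` (named masses
#'   for costed acute events)
#' @export
mortality_step <- function(state, context, life_table, tables) {
  if (inherits(tables, "dm_params")) tables <- compile_tables(tables)
  A0 <- state$alive
  d_bg <- 0
  if (!is.null(life_table)) {
    if (context$age > max(life_table$age)) {
      stop("age ", context$age, " beyond life table range")
    }
    q <- life_table_q(life_table, context$age, context$sex)
    d_bg <- state$alive * q
    state$alive <- state$alive * (1 - q)
  }
  A <- state$alive

  # effective acute incidence under treatment
  p_str <- stroke_incidence(context, tables$stroke_model)
  tt <- min(max(context$t_onset, 1), length(tables$chd_p))
  p_chd <- tables$chd_p[tt]
  eff <- apply_treatment_effects(c(stroke = p_str, chd = p_chd),
                                 context, tables$effects)

  # stroke track (conditional fractions)
  s <- state$stroke
  ev_str <- s[1] * eff[["stroke"]]
  d_imm <- ev_str * tables$cf_stroke_imm
  d_y1 <- s[2] * tables$cf_stroke_yr1
  s_new <- c(s[1] - ev_str, ev_str - d_imm, s[3] + s[2] - d_y1)
  d_stroke_frac <- d_imm + d_y1

  # CHD track
  cc <- state$chd
  ev_chd <- cc[1] * eff[["chd"]]
  ev_mi <- ev_chd * tables$mi_fraction
  ev_ang <- ev_chd - ev_mi
  d_mi <- ev_mi * tables$mi_cf
  c_new <- c(cc[1] - ev_chd, cc[2] + ev_ang, cc[3] + ev_mi - d_mi)
  d_chd_frac <- d_mi

  # renal track: ESRD excess mortality (0 when not configured)
  rr <- state$renal
  d_esrd_frac <- rr[4] * tables$p_esrd_death
  r_new <- c(rr[1], rr[2], rr[3], rr[4] - d_esrd_frac)

  # joint survival multiplies across tracks; other tracks' conditional
  # distributions are unaffected by these deaths
  surv <- (1 - d_stroke_frac) * (1 - d_chd_frac) * (1 - d_esrd_frac)
  alive_new <- A * surv
  d_total_acute <- A - alive_new
  d_sum <- d_stroke_frac + d_chd_frac + d_esrd_frac
  shares <- if (d_sum > 0) {
    c(d_stroke_frac, d_chd_frac, d_esrd_frac) / d_sum
  } else c(0, 0, 0)

  state$alive <- alive_new
  state$stroke <- if (d_stroke_frac < 1) s_new / (1 - d_stroke_frac) else s_new * 0
  state$chd <- if (d_chd_frac < 1) c_new / (1 - d_chd_frac) else c_new * 0
  state$renal <- if (d_esrd_frac < 1) r_new / (1 - d_esrd_frac) else r_new * 0

  deaths <- c(background = d_bg,
              stroke = d_total_acute * shares[1],
              chd = d_total_acute * shares[2],
              esrd = d_total_acute * shares[3])
  deaths <- c(deaths, total = sum(deaths))
  events <- c(
    stroke = A * ev_str,
    stroke_death_imm = A * d_imm,
    stroke_surv = A * (ev_str - d_imm),
    angina = A * ev_ang,
    mi = A * ev_mi,
    mi_surv = A * (ev_mi - d_mi),
    mi_death_nohosp = A * d_mi * tables$mi_nh_share,
    mi_death_hosp = A * d_mi * (1 - tables$mi_nh_share)
  )
  list(state = state, deaths = deaths, events = events)
}

#' Chronic complication-track transitions for one cycle
#'
#' Advances the renal (normal, microalbuminuria, nephropathy, end-stage
#' renal disease), neuropathy (normal, peripheral neuropathy, amputation)
#' and retinal (normal, photocoagulation, blindness) tracks one annual
#' step, drawing probabilities from the hypertension-control stratum and
#' the years-since-diagnosis band implied by the context, with
#' intensified-glycemic hazard multipliers where applicable. Tracks
#' advance at most one state per cycle; no deaths occur here, so mass is
#' conserved exactly.
#'
#' The duration bands of the nephropathy-to-ESRD and neuropathy-to-
#' amputation probabilities encode disease-duration gradients; the engine
#' indexes them by years since onset (`context$duration`), which is
#' invariant to when diagnosis happens, so that earlier detection shifts
#' treatment, not the underlying progression clock. (Indexing by years
#' since diagnosis would make screening advance the band clock itself —
#' a pure lead-time artifact that penalizes detection.)
#'
#' @inheritParams mortality_step
#' @return list with `state` and `events` (named masses of new entries
#'   into each chronic state)
#' @export
annual_transition <- function(state, context, tables) {
  if (inherits(tables, "dm_params")) tables <- compile_tables(tables)
  st <- ctx_stratum(context)
  ysd <- min(max(context$duration %||% context$ysd %||% 0, 0), 94) + 1L
  base <- c(
    microalbuminuria = tables$p_micro[[st]],
    nephropathy = tables$p_neph[[st]],
    neuropathy = tables$p_pn,
    photocoagulation = tables$p_photo[[st]]
  )
  eff <- apply_treatment_effects(base, context, tables$effects)
  A <- state$alive

  r <- state$renal
  f1 <- r[1] * eff[["microalbuminuria"]]
  f2 <- r[2] * eff[["nephropathy"]]
  f3 <- r[3] * tables$p_esrd[ysd]
  state$renal <- c(r[1] - f1, r[2] + f1 - f2, r[3] + f2 - f3, r[4] + f3)

  n <- state$neuro
  g1 <- n[1] * eff[["neuropathy"]]
  g2 <- n[2] * tables$p_lea[ysd]
  state$neuro <- c(n[1] - g1, n[2] + g1 - g2, n[3] + g2)

  e <- state$retina
  h1 <- e[1] * eff[["photocoagulation"]]
  h2 <- e[2] * tables$p_blind[[st]]
  state$retina <- c(e[1] - h1, e[2] + h1 - h2, e[3] + h2)

  events <- c(microalbuminuria = f1, nephropathy = f2, esrd = f3,
              pn = g1, lea = g2, photo = h1, blind = h2) * A
  list(state = state, events = events)
}

# ---- lifetime simulation ---------------------------------------------------

.traj_cols <- c(
  "stratum_id", "cycle", "age", "treated", "ysd", "ht", "alive",
  paste0("occ_", c(.renal_states, .neuro_states, .retina_states,
                   .chd_states, .stroke_states)),
  "ev_microalbuminuria", "ev_nephropathy", "ev_esrd", "ev_pn", "ev_lea",
  "ev_photo", "ev_blind", "ev_angina", "ev_mi", "ev_mi_surv",
  "ev_mi_death_nohosp", "ev_mi_death_hosp", "ev_stroke", "ev_stroke_surv",
  "ev_stroke_death_imm", "d_background", "d_stroke", "d_chd", "d_esrd",
  "d_total"
)

#' Simulate lifetime disease progression for a cohort arm
#'
#' Deterministic expected-value evolution of every undiagnosed-diabetes
#' stratum of the cohort through the complication tracks, from the
#' screening epoch (cycle 0) until the alive mass is exhausted or the
#' age cap is reached. Cycle order: background mortality, acute events
#' (stroke / CHD) with case fatality, chronic-track transitions, with
#' occupancy recorded at end of cycle.
#'
#' Each stratum entered the diseased state `onset_years` before cycle 0;
#' those pre-screening years are run as a burn-in (untreated hazards,
#' survival conditioned away, since the stratum mass is the prevalence
#' observed at screening) to set the complication mix at cycle 0.
#' Diagnosis occurs `lead_time_years - onset_years` cycles after
#' screening in the unscreened arm; in the screened arm, cases detected
#' at screening have this interval shortened by `detection_benefit_years`
#' (floored at 0, i.e. diagnosis at cycle 0), while screen-missed cases
#' follow the unscreened clock. Treatment status flips in the diagnosis
#' cycle; intensified glycemic (and, for hypertensives, hypertension)
#' control then applies unless `intensive = FALSE` (the
#' no-intensive-control comparator).
#'
#' @param cohort a `dm_cohort`; for `arm = "screened"` it must carry the
#'   `detected` column produced by [screen_cohort()]
#' @param arm `"screened"` or `"unscreened"`
#' @param params a `dm_params` bundle
#' @param life_table a `dm_life_table` (default [generate_life_table()])
#' @param intensive do diagnosed persons receive intensified control in
#'   this arm? (default TRUE; FALSE only for the comparator scenario)
#' @return a `dm_trajectory` data.frame: one row per stratum and cycle
#'   with end-of-cycle occupancy masses (`occ_*`), event masses (`ev_*`)
#'   and cause-tagged deaths (`d_*`); attributes `arm`, `n_cases` (total
#'   undiagnosed mass), `strata`
#' @export
simulate_lifetime <- function(cohort, arm = c("screened", "unscreened"),
                              params, life_table = generate_life_table(),
                              intensive = TRUE) {
  arm <- match.arg(arm)
  sc <- params$screening
  cases <- cohort[cohort$diabetes == "undiagnosed" & cohort$mass > 0, ,
                  drop = FALSE]
  if (arm == "screened" && is.null(cases$detected)) {
    stop("screened arm requires a cohort processed by screen_cohort()")
  }
  tables <- compile_tables(params)
  age_cap <- params$settings$age_cap
  if (!nrow(cases)) {
    empty <- as.data.frame(matrix(numeric(0), ncol = length(.traj_cols),
                                  dimnames = list(NULL, .traj_cols)))
    return(structure(empty, class = c("dm_trajectory", "data.frame"),
                     arm = arm, n_cases = 0, strata = cases,
                     intensive = intensive))
  }
  out <- vector("list", nrow(cases))

  for (i in seq_len(nrow(cases))) {
    row <- cases[i, ]
    tau0 <- row$onset_years
    diag_delay <- if (arm == "screened" && isTRUE(row$detected)) {
      max(0, sc$lead_time_years - tau0 - sc$detection_benefit_years)
    } else {
      sc$lead_time_years - tau0
    }
    ctx <- list(sex = row$sex, hypertensive = row$hypertensive,
                intensive = intensive, p_smoking = row$p_smoking,
                p_hchol = row$p_hchol)

    state <- dm_state(row$mass)
    # burn-in: onset to screening, untreated, survival conditioned away
    if (tau0 > 0) {
      for (j in seq_len(tau0)) {
        ctx$age <- row$age - tau0 + (j - 1)
        ctx$treated <- FALSE
        ctx$ysd <- 0
        ctx$duration <- j - 1
        ctx$t_onset <- j
        state <- mortality_step(state, ctx, NULL, tables)$state
        state <- annual_transition(state, ctx, tables)$state
      }
      state$alive <- row$mass  # condition on being alive at screening
    }

    n_cyc <- max(age_cap - row$age, 0)
    m <- matrix(0, nrow = n_cyc, ncol = length(.traj_cols),
                dimnames = list(NULL, .traj_cols))
    used <- 0L
    for (cyc in seq_len(n_cyc) - 1L) {
      if (state$alive < 1e-12) break
      ctx$age <- row$age + cyc
      ctx$treated <- cyc >= diag_delay
      ctx$ysd <- max(0, cyc - diag_delay)
      ctx$duration <- tau0 + cyc
      ctx$t_onset <- tau0 + cyc + 1
      ms <- mortality_step(state, ctx, life_table, tables)
      at <- annual_transition(ms$state, ctx, tables)
      state <- at$state
      used <- used + 1L
      m[used, ] <- c(
        i, cyc, ctx$age, as.numeric(ctx$treated), ctx$ysd,
        as.numeric(row$hypertensive), state$alive,
        state$alive * c(state$renal, state$neuro, state$retina,
                        state$chd, state$stroke),
        at$events[c("microalbuminuria", "nephropathy", "esrd", "pn", "lea",
                    "photo", "blind")],
        ms$events[c("angina", "mi", "mi_surv", "mi_death_nohosp",
                    "mi_death_hosp", "stroke", "stroke_surv",
                    "stroke_death_imm")],
        ms$deaths[c("background", "stroke", "chd", "esrd", "total")]
      )
    }
    out[[i]] <- m[seq_len(used), , drop = FALSE]
  }

  traj <- as.data.frame(do.call(rbind, out))
  strata <- cases
  strata$stratum_id <- seq_len(nrow(cases))
  structure(traj, class = c("dm_trajectory", "data.frame"),
            arm = arm, n_cases = sum(cases$mass), strata = strata,
            intensive = intensive)
}

#' @export
print.dm_trajectory <- function(x, ...) {
  cat("<dm_trajectory> arm:", attr(x, "arm"),
      "|", length(unique(x$stratum_id)), "strata,",
      nrow(x), "stratum-cycles | cases:", format(attr(x, "n_cases")), "\n")
  invisible(x)
}

#' Lifetime cumulative incidence of the modelled complications
#'
#' Sums event masses over the whole trajectory and normalizes per true
#' case of diabetes, giving the lifetime cumulative incidence of
#' end-stage renal disease, lower-extremity amputation, stroke, CHD and
#' blindness (as percentages).
#'
#' @param trajectory a `dm_trajectory`
#' @return named numeric vector of cumulative incidences in percent
#' @export
cumulative_incidence <- function(trajectory) {
  n <- attr(trajectory, "n_cases")
  100 * c(
    esrd = sum(trajectory$ev_esrd),
    lea = sum(trajectory$ev_lea),
    stroke = sum(trajectory$ev_stroke),
    chd = sum(trajectory$ev_angina) + sum(trajectory$ev_mi),
    blindness = sum(trajectory$ev_blind)
  ) / n
}
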