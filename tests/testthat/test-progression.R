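test_that("Weibull CHD incidence matches its closed forms", {
  # shape 1: exponential, memoryless -> constant discrete hazard
  m <- list(shape = 1, scale = 20)
  expect_equal(chd_incidence(1:5, m), rep(1 - exp(-1 / 20), 5),
               tolerance = 1e-12)
  # t = 1 with F(0) = 0 is just F(1)
  m2 <- list(shape = 2, scale = 30)
  expect_equal(chd_incidence(1, m2), pweibull(1, 2, 30))
  # shape 2, scale 30, t = 10: (F(10) - F(9)) / (1 - F(9))
  expect_equal(chd_incidence(10, m2), 1 - exp(-(100 - 81) / 900),
               tolerance = 1e-12)
  expect_error(chd_incidence(0, m2), ">= 1")
  expect_error(chd_incidence(5, list(shape = 2, scale = 1e-4)), "exhausted")
})

test_that("multi-year risks convert to annual probabilities", {
  expect_equal(annualize_risk(0.2), 1 - 0.8^0.1, tolerance = 1e-12)
  expect_equal(annualize_risk(0), 0)
})

test_that("stroke incidence: exact table lookup and equation mode", {
  p <- test_params()
  tb <- p$stroke_model$table
  row <- tb[tb$sex == "male" & tb$hypertensive & tb$age_lo == 60, ]
  got <- stroke_incidence(list(age = 62, sex = "male", hypertensive = TRUE),
                          p$stroke_model)
  expect_equal(got, row$prob)
  expect_error(
    stroke_incidence(list(age = 20, sex = "male", hypertensive = FALSE),
                     p$stroke_model), "no stroke table entry")

  eq <- list(mode = "equation",
             coef = c(s0 = 0.9, age = 0, male = 0, hypertension = 0,
                      smoking = 0, hchol = 0))
  # all coefficients zero: the baseline-survival-implied probability only
  expect_equal(
    stroke_incidence(list(age = 70, sex = "male", hypertensive = TRUE), eq),
    annualize_risk(0.1), tolerance = 1e-12)

  eq$coef <- c(s0 = 0.9, age = 0.05, male = 0.3, hypertension = 0.5,
               smoking = 0.4, hchol = 0.2)
  ctx <- list(age = 60, sex = "female", hypertensive = TRUE)
  p_non <- stroke_incidence(c(ctx, p_smoking = 0), eq)
  p_smk <- stroke_incidence(c(ctx, p_smoking = 1), eq)
  # fractional covariates mix exactly
  expect_equal(stroke_incidence(c(ctx, p_smoking = 0.3), eq),
               0.3 * p_smk + 0.7 * p_non, tolerance = 1e-12)
  expect_gt(p_smk, p_non)

  eq$coef <- eq$coef[names(eq$coef) != "smoking"]
  expect_error(stroke_incidence(ctx, eq), "missing")
})

test_that("treatment effects adjust the stated pathways only", {
  eff <- test_params()$treatment_effects
  on_treat <- list(treated = TRUE, intensive = TRUE, hypertensive = TRUE)

  # 17-44% stroke RRR: at 0.44, 0.10 -> 0.056; CHD 13%: 0.05 -> 0.0435
  got <- apply_treatment_effects(c(stroke = 0.10, chd = 0.05), on_treat, eff)
  expect_equal(got[["stroke"]], 0.056, tolerance = 1e-12)
  expect_equal(got[["chd"]], 0.0435, tolerance = 1e-12)

  # microvascular multipliers under intensified glycemic control
  base <- c(microalbuminuria = 0.033, nephropathy = 0.075,
            neuropathy = 0.0036, photocoagulation = 0.011)
  got <- apply_treatment_effects(base, on_treat, eff)
  expect_equal(unname(got), unname(base * eff$glycemic_micro[names(base)]))

  # untreated, or effects disabled: probabilities unchanged
  expect_equal(apply_treatment_effects(base, list(treated = FALSE), eff), base)
  null_eff <- eff
  null_eff$glycemic_micro[] <- 1
  null_eff$hypertension_rr[] <- 0
  expect_equal(
    apply_treatment_effects(c(base, stroke = 0.1, chd = 0.05), on_treat,
                            null_eff),
    c(base, stroke = 0.1, chd = 0.05))

  # base case: no glycemic effect on macrovascular outcomes for
  # non-hypertensives
  got <- apply_treatment_effects(
    c(stroke = 0.10, chd = 0.05),
    list(treated = TRUE, intensive = TRUE, hypertensive = FALSE), eff)
  expect_equal(got, c(stroke = 0.10, chd = 0.05))
})

test_that("one chronic cycle moves the printed probability masses", {
  p <- test_params()
  ctx <- list(treated = FALSE, intensive = TRUE, hypertensive = FALSE,
              ysd = 0, duration = 0, t_onset = 1)
  st <- dm_state(1)
  res <- annual_transition(st, ctx, p)
  expect_equal(res$state$renal, c(0.967, 0.033, 0, 0))
  expect_equal(res$events[["microalbuminuria"]], 0.033)
  expect_equal(res$state$neuro[2], 0.0036)
  expect_equal(res$state$retina[2], 0.011)
  # track distributions remain distributions (mass conserved per track)
  for (tk in c("renal", "neuro", "retina", "chd", "stroke")) {
    expect_equal(sum(res$state[[tk]]), 1, tolerance = 1e-15)
  }

  # nephropathy mass at 15 in-band years progresses to ESRD at 0.039
  st$renal <- c(0, 0, 1, 0)
  ctx15 <- ctx
  ctx15$duration <- 15
  res <- annual_transition(st, ctx15, p)
  expect_equal(res$state$renal[4], 0.039)

  # with an all-zero table nothing moves
  res0 <- annual_transition(dm_state(1), ctx, inert_params())
  expect_equal(res0$state, dm_state(1))
})

test_that("mortality step applies case fatality and background death", {
  p <- test_params()
  lt <- no_mortality_life_table()
  ctx <- list(age = 60, sex = "male", hypertensive = FALSE, treated = FALSE,
              intensive = TRUE, t_onset = 5, ysd = 0, duration = 4)

  # a guaranteed stroke event (and no other hazard) kills 14.2%
  # immediately
  p_sure <- inert_params()
  cf <- p_sure$transitions$from == "stroke_event"
  p_sure$transitions$prob[cf] <- c(0.142, 0.092)
  p_sure$stroke_model$table$prob <- 1
  res <- mortality_step(dm_state(1), ctx, lt, p_sure)
  expect_equal(res$events[["stroke"]], 1)
  expect_equal(res$deaths[["stroke"]], 0.142)
  expect_equal(res$events[["stroke_death_imm"]], 0.142)
  # survivors sit in the first post-stroke year
  expect_equal(res$state$stroke[2], 1)
  expect_equal(res$state$alive, 0.858)

  # next cycle the first-year excess mortality applies, then survivors
  # join the post-stroke history state
  res2 <- mortality_step(res$state, ctx, lt, p_sure)
  expect_equal(res2$deaths[["total"]], 0.858 * 0.092, tolerance = 1e-9)
  expect_equal(res2$state$stroke[3], 1)

  # no hazards anywhere: no deaths
  res0 <- mortality_step(dm_state(1), ctx, lt, inert_params())
  expect_equal(res0$deaths[["total"]], 0)

  # certain background mortality absorbs everyone
  lt1 <- lt
  lt1$q[] <- 1
  res1 <- mortality_step(dm_state(1), ctx, lt1, inert_params())
  expect_equal(res1$state$alive, 0)
  expect_equal(res1$deaths[["background"]], 1)

  expect_error(
    mortality_step(dm_state(1), list(age = 150, sex = "male"), lt, p),
    "life table")
})

test_that("lifetime simulation conserves mass to 1e-12 every cycle", {
  p <- test_params()
  co <- generate_cohort(brazil_prevalence_surface(), 1000, "expected",
                        onset_years_at_screening = 5)
  scr <- screen_cohort(co, p$screening)
  for (traj in list(simulate_lifetime(co, "unscreened", p),
                    simulate_lifetime(scr$cohort, "screened", p))) {
    expect_lt(max_conservation_error(traj) / 1000, 1e-12)
  }
})

test_that("an empty cohort yields an empty trajectory and zero ledger", {
  p <- test_params()
  co <- one_case_cohort(mass = 0)
  traj <- simulate_lifetime(co, "unscreened", p)
  expect_equal(nrow(traj), 0)
  led <- accrue(traj, p$costs, p$utilities, p$settings)
  expect_equal(led$totals$cost_total, 0)
  expect_equal(led$totals$qaly, 0)
})

test_that("cohort engine matches the Monte Carlo oracle on a toy chain", {
  p <- toy_chain_params(p01 = 0.08, p12 = 0.05)
  lt <- no_mortality_life_table()
  cycles <- 10L
  co <- one_case_cohort(age = 50, sex = "female", hypertensive = FALSE,
                        tau0 = 0)
  traj <- simulate_lifetime(co, "unscreened", p, lt)
  eng <- traj[traj$cycle == cycles - 1,
              c("occ_renal_normal", "occ_microalbuminuria", "occ_nephropathy")]
  n <- 1e6
  mc <- mc_simulate(n, p, lt, age0 = 50, sex = "female", hypertensive = FALSE,
                    tau0 = 0, diag_delay = 10, cycles = cycles, seed = 2024)
  expect_within_3se(mc$renal[1:3], as.numeric(eng), n, "toy chain occupancy")
  expect_equal(mc$alive, 1)  # nobody dies in the toy chain
})

test_that("cohort engine matches the Monte Carlo oracle on the full model", {
  p <- test_params()
  lt <- generate_life_table()
  cycles <- 5L
  tau0 <- 6L
  co <- one_case_cohort(age = 52, sex = "male", hypertensive = TRUE,
                        tau0 = tau0)
  traj <- simulate_lifetime(co, "unscreened", p, lt)  # diagnosis at cycle 4
  row <- traj[traj$cycle == cycles - 1, ]
  n <- 1e6
  mc <- mc_simulate(n, p, lt, age0 = 52, sex = "male", hypertensive = TRUE,
                    tau0 = tau0, diag_delay = 10 - tau0, cycles = cycles,
                    seed = 31)
  expect_within_3se(mc$alive, row$alive, mc$n, "alive")
  expect_within_3se(mc$renal,
                    as.numeric(row[paste0("occ_", c("renal_normal",
                      "microalbuminuria", "nephropathy", "esrd"))]),
                    mc$n, "renal")
  expect_within_3se(mc$neuro,
                    as.numeric(row[paste0("occ_", c("neuro_normal",
                      "peripheral_neuropathy", "lea"))]), mc$n, "neuro")
  expect_within_3se(mc$retina,
                    as.numeric(row[paste0("occ_", c("retina_normal",
                      "photocoagulation", "blindness"))]), mc$n, "retina")
  expect_within_3se(mc$chd,
                    as.numeric(row[paste0("occ_", c("chd_none", "angina",
                      "history_ca_mi"))]), mc$n, "chd")
  expect_within_3se(mc$stroke,
                    as.numeric(row[paste0("occ_", c("stroke_none",
                      "stroke_year1", "stroke_history"))]), mc$n, "stroke")
})

test_that("screened and unscreened arms coincide without detection benefit", {
  p <- perturb_params(test_params(), "detection_benefit_years", value = 0)
  res <- run_cea(p, cohort_size = 1e4)
  expect_equal(res$ce$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(res$ce$delta_ly, 0, tolerance = 1e-12)
  # the only incremental cost is the screening program itself
  scr_per_case <- (res$screening$screening_cost_total +
                     res$screening$confirmation_cost_total) / res$n_cases
  expect_equal(res$ce$delta_cost, scr_per_case, tolerance = 1e-10)
  expect_equal(res$incidence$screened, res$incidence$unscreened,
               tolerance = 1e-12)
})

test_that("screening lowers lifetime incidence of every complication", {
  res <- cached_base_run()
  expect_true(all(res$incidence$screened < res$incidence$unscreened))
})
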