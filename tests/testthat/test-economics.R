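# a one-row trajectory for hand-checkable accrual
single_row_traj <- function(cycle = 0, alive = 1, occ = list(), ev = list(),
                            d_total = 0, treated = 0, ht = 0, ysd = 0,
                            n_cases = 1) {
  cols <- dmscreen:::.traj_cols
  m <- as.data.frame(matrix(0, nrow = length(cycle), ncol = length(cols),
                            dimnames = list(NULL, cols)))
  m$stratum_id <- 1
  m$cycle <- cycle
  m$age <- 60 + cycle
  m$alive <- alive
  m$occ_renal_normal <- alive
  m$occ_neuro_normal <- alive
  m$occ_retina_normal <- alive
  m$occ_chd_none <- alive
  m$occ_stroke_none <- alive
  m$treated <- treated
  m$ht <- ht
  m$ysd <- ysd
  m$d_total <- d_total
  for (nm in names(occ)) {
    m[[paste0("occ_", nm)]] <- occ[[nm]]
    m$occ_renal_normal <- m$occ_renal_normal -
      if (nm %in% c("microalbuminuria", "nephropathy", "esrd")) occ[[nm]] else 0
  }
  for (nm in names(ev)) m[[paste0("ev_", nm)]] <- ev[[nm]]
  structure(m, class = c("dm_trajectory", "data.frame"), arm = "test",
            n_cases = n_cases, intensive = TRUE)
}

flat_utilities <- function(u = 1) {
  data.frame(state = c("no_complication", "microalbuminuria", "nephropathy",
                       "esrd", "peripheral_neuropathy", "lea",
                       "photocoagulation", "blindness", "angina",
                       "history_ca_mi", "stroke", "death"),
             utility = c(rep(u, 11), 0))
}

test_that("discount factors follow (1 + r)^-t", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(7, 0), 1)
  expect_equal(sum(discount_factor(0:2, 0.05)), 1 + 1 / 1.05 + 1 / 1.05^2,
               tolerance = 1e-12)
  expect_equal(sum(discount_factor(0:2, 0.05)), 2.85941043, tolerance = 1e-8)
  expect_error(discount_factor(-1, 0.05), ">= 0")
})

test_that("accrual charges the printed unit costs", {
  p <- test_params()
  st <- p$settings
  st$discount_rate <- 0

  # one undiscounted person-year in ESRD costs 9,527 US$
  tr <- single_row_traj(occ = list(esrd = 1))
  led <- accrue(tr, p$costs, p$utilities, st)
  expect_equal(led$totals$complications, 9527)
  expect_equal(led$totals$background_care, 94)

  # one person-year at utility 1 in year 1 at 5% discounts to 1/1.05
  st5 <- p$settings
  tr1 <- single_row_traj(cycle = 1)
  led1 <- accrue(tr1, p$costs, flat_utilities(1), st5)
  expect_equal(led1$totals$qaly, 1 / 1.05, tolerance = 1e-12)
  expect_equal(led1$totals$qaly, 0.952381, tolerance = 1e-6)
  expect_equal(led1$totals$ly, 1 / 1.05)

  # one-time event costs land once, in the event cycle
  tr2 <- single_row_traj(ev = list(stroke_surv = 1, lea = 1), d_total = 0.1)
  led2 <- accrue(tr2, p$costs, p$utilities, st)
  expect_equal(led2$totals$complications, 955 + 309)
  expect_equal(led2$totals$death, 0.1 * 304)

  # missing cost or utility entries are named
  broken <- p$costs
  broken$complications <- broken$complications[
    broken$complications$item != "esrd", ]
  expect_error(accrue(tr, broken, p$utilities, st), "esrd")
  expect_error(accrue(tr, p$costs, p$utilities[-1, ], st), "no_complication")
})

test_that("treatment and intensified-control costs follow diagnosis", {
  p <- test_params()
  st <- p$settings
  st$discount_rate <- 0
  tr <- single_row_traj(treated = 1, ht = 1, ysd = 0)
  led <- accrue(tr, p$costs, p$utilities, st)
  expect_equal(led$totals$treatment, p$costs$standard_glycemic_annual$usd[1])
  expect_equal(led$totals$intensified_control,
               p$costs$intensified_glycemic_annual$usd[1] +
                 p$costs$intensified_hypertension_annual)
  # years-since-diagnosis band switches the treatment price
  tr2 <- single_row_traj(treated = 1, ht = 0, ysd = 12)
  led2 <- accrue(tr2, p$costs, p$utilities, st)
  expect_equal(led2$totals$treatment, p$costs$standard_glycemic_annual$usd[2])
  # no intensified costs accrue in a non-intensive arm
  attr(tr, "intensive") <- FALSE
  expect_equal(accrue(tr, p$costs, p$utilities, st)$totals$intensified_control,
               0)
})

test_that("utility decrements combine additively over tracks", {
  p <- test_params()
  st <- p$settings
  st$discount_rate <- 0
  u <- p$utilities
  u0 <- u$utility[u$state == "no_complication"]
  dec_esrd <- u0 - u$utility[u$state == "esrd"]
  dec_blind <- u0 - u$utility[u$state == "blindness"]
  tr <- single_row_traj(occ = list(esrd = 0.3, blindness = 0.2))
  led <- accrue(tr, p$costs, u, st)
  expect_equal(led$totals$qaly, u0 - 0.3 * dec_esrd - 0.2 * dec_blind,
               tolerance = 1e-12)
})

test_that("ledger totals are additive and discounting is linear", {
  res <- cached_base_run()
  for (led in res$ledgers) {
    cats <- c("treatment", "complications", "screening",
              "intensified_control", "background_care", "death")
    expect_equal(led$totals$cost_total,
                 sum(unlist(led$totals[cats])),
                 tolerance = 1e-9 * led$totals$cost_total)
    expect_equal(sum(led$by_cycle$cost_total), led$totals$cost_total)
  }

  # accrue at rate r equals undiscounted per-cycle accruals dotted with
  # the discount factors
  p <- test_params()
  traj <- res$trajectories$unscreened
  st0 <- p$settings
  st0$discount_rate <- 0
  led0 <- accrue(traj, p$costs, p$utilities, st0)
  led5 <- accrue(traj, p$costs, p$utilities, p$settings)
  df <- discount_factor(led0$by_cycle$cycle, 0.05)
  for (col in c("cost_total", "qaly", "ly")) {
    expect_equal(sum(led0$by_cycle[[col]] * df), led5$totals[[col]],
                 tolerance = 1e-9)
  }
})

test_that("ICER computation handles dominance and rounding", {
  r <- icer(489, 0.0157)
  expect_equal(r$icer, 489 / 0.0157, tolerance = 1e-12)
  expect_equal(r$dominance, "none")

  expect_equal(icer(0, 0.01)$icer, 0)
  expect_equal(icer(-10, 0.01)$dominance, "dominant")
  expect_equal(icer(10, -0.01)$dominance, "dominated")
  expect_true(is.na(icer(10, -0.01)$icer))
  expect_equal(icer(10, 0)$dominance, "undefined")
  expect_equal(icer(0, 0)$dominance, "none")

  # reporting rounds half away from zero
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(2.449), 2)
})

test_that("swapping arms negates both deltas", {
  res <- cached_base_run()
  fwd <- compute_icer(res$ledgers$screened, res$ledgers$unscreened)
  rev <- compute_icer(res$ledgers$unscreened, res$ledgers$screened)
  expect_equal(rev$delta_cost, -fwd$delta_cost)
  expect_equal(rev$delta_qaly, -fwd$delta_qaly)
  expect_equal(rev$icer, fwd$icer)  # ratio of negated deltas
})

test_that("currency conversion applies the market and PPP rates", {
  st <- test_params()$settings
  expect_equal(convert_currency(0, st), 0)
  expect_equal(convert_currency(1, st), 2.35 / 0.59, tolerance = 1e-12)
  expect_equal(round_half_away(convert_currency(31147, st)), 124060)
  expect_equal(round_half_away(convert_currency(22695, st)), 90395)
  expect_equal(round_half_away(convert_currency(26.19, st), 2), 104.32)
})

test_that("the summary table has the three strategy rows and consistent deltas", {
  res <- cached_base_run()
  s <- res$summary
  expect_equal(s$strategy, c("no_screening", "screening", "incremental"))
  expect_equal(s$cost_total[3], s$cost_total[2] - s$cost_total[1],
               tolerance = 1e-9)
  expect_equal(s$qaly[3], res$ce$delta_qaly, tolerance = 1e-12)
  expect_equal(s$icer_usd_per_qaly[3], res$ce$icer_reported)
})
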