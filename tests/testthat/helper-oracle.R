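# Individual-level Monte Carlo oracle for the cohort engine: simulates n
# independent individuals through exactly the joint model the engine
# integrates in expectation (background death first, then independent
# per-track exits — death on any track exit — then chronic single-step
# advances computed from start-of-step states). Used to cross-check the
# deterministic expected-value engine.

mc_simulate <- function(n, params, life_table, age0, sex, hypertensive,
                        tau0, diag_delay, cycles, seed, intensive = TRUE) {
  set.seed(seed)
  tb <- dmscreen:::compile_tables(params)
  renal <- rep(1L, n); neuro <- rep(1L, n); retina <- rep(1L, n)
  chd <- rep(1L, n); stroke <- rep(1L, n); alive <- rep(TRUE, n)

  run_cycle <- function(cyc, burnin) {
    age <- if (burnin) age0 - tau0 + cyc else age0 + cyc
    treated <- !burnin && cyc >= diag_delay
    dur <- if (burnin) cyc else tau0 + cyc
    on_intensive <- treated && intensive
    st <- if (!hypertensive) "baseline" else if (on_intensive) "tight" else "moderate"
    gm <- if (on_intensive) tb$effects$glycemic_micro else
      c(microalbuminuria = 1, nephropathy = 1, neuropathy = 1,
        photocoagulation = 1)
    macro <- function(endpoint) {
      m <- 1
      if (on_intensive) {
        m <- m * (1 - tb$effects$glycemic_macro_rr[[endpoint]])
        if (hypertensive) m <- m * (1 - tb$effects$hypertension_rr[[endpoint]])
      }
      m
    }
    # 1. background mortality
    if (!burnin) {
      q <- dmscreen:::life_table_q(life_table, age, sex)
      alive[alive & stats::runif(n) < q] <<- FALSE
    }
    # 2. acute events and track deaths, from start-of-step states
    p_str <- stroke_incidence(
      list(age = age, sex = sex, hypertensive = hypertensive),
      tb$stroke_model) * macro("stroke")
    p_chd <- tb$chd_p[min(dur + 1, length(tb$chd_p))] * macro("chd")
    ev_str <- alive & stroke == 1L & stats::runif(n) < p_str
    u_cf <- stats::runif(n)
    d_imm <- ev_str & u_cf < tb$cf_stroke_imm
    y1 <- alive & stroke == 2L
    d_y1 <- y1 & u_cf < tb$cf_stroke_yr1
    ev_chd <- alive & chd == 1L & stats::runif(n) < p_chd
    is_mi <- ev_chd & stats::runif(n) < tb$mi_fraction
    d_mi <- is_mi & stats::runif(n) < tb$mi_cf
    d_esrd <- alive & renal == 4L & stats::runif(n) < tb$p_esrd_death
    stroke[ev_str] <<- 2L
    stroke[y1] <<- 3L
    chd[ev_chd & !is_mi] <<- 2L
    chd[is_mi] <<- 3L
    alive[d_imm | d_y1 | d_mi | d_esrd] <<- FALSE
    # 3. chronic single-step advances from start-of-step states
    r1 <- alive & renal == 1L &
      stats::runif(n) < tb$p_micro[[st]] * gm[["microalbuminuria"]]
    r2 <- alive & renal == 2L &
      stats::runif(n) < tb$p_neph[[st]] * gm[["nephropathy"]]
    r3 <- alive & renal == 3L & stats::runif(n) < tb$p_esrd[min(dur, 94) + 1]
    renal[r1] <<- 2L; renal[r2] <<- 3L; renal[r3] <<- 4L
    n1 <- alive & neuro == 1L & stats::runif(n) < tb$p_pn * gm[["neuropathy"]]
    n2 <- alive & neuro == 2L & stats::runif(n) < tb$p_lea[min(dur, 94) + 1]
    neuro[n1] <<- 2L; neuro[n2] <<- 3L
    e1 <- alive & retina == 1L &
      stats::runif(n) < tb$p_photo[[st]] * gm[["photocoagulation"]]
    e2 <- alive & retina == 2L & stats::runif(n) < tb$p_blind[[st]]
    retina[e1] <<- 2L; retina[e2] <<- 3L
    invisible(NULL)
  }

  if (tau0 > 0) {
    for (j in seq_len(tau0) - 1L) run_cycle(j, burnin = TRUE)
    keep <- alive  # condition on surviving to the screening epoch
    renal <- renal[keep]; neuro <- neuro[keep]; retina <- retina[keep]
    chd <- chd[keep]; stroke <- stroke[keep]
    n <- sum(keep)
    alive <- rep(TRUE, n)
  }
  n0 <- n
  for (cyc in seq_len(cycles) - 1L) run_cycle(cyc, burnin = FALSE)

  frac <- function(track, k) {
    vapply(seq_len(k), function(s) sum(alive & track == s) / n0, numeric(1))
  }
  list(n = n0, alive = sum(alive) / n0,
       renal = frac(renal, 4), neuro = frac(neuro, 3),
       retina = frac(retina, 3), chd = frac(chd, 3),
       stroke = frac(stroke, 3))
}

# three-standard-error comparison of a Monte Carlo proportion against the
# engine's expected value
expect_within_3se <- function(p_hat, p, n, label) {
  se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
  testthat::expect_true(
    all(abs(p_hat - p) <= 3 * se + 1e-9),
    label = paste0(label, ": max |dev|/se = ",
                   round(max(abs(p_hat - p) / se), 2))
  )
}
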