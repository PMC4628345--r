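# Shared fixtures: the bundled base case is loaded once per test run;
# engine tests use reduced bundles derived from it.

.fixtures <- new.env(parent = emptyenv())

test_params <- function() {
  if (is.null(.fixtures$bp)) .fixtures$bp <- brazil_params()
  .fixtures$bp
}

# a bundle in which nothing happens: all transition probabilities zero,
# no stroke risk, negligible CHD hazard
inert_params <- function() {
  p <- test_params()
  p$transitions$prob <- 0
  p$stroke_model$table$prob <- 0
  p$chd_model$scale <- 1e9
  p
}

# three-state toy chain: only the renal track moves
# (normal -> microalbuminuria -> nephropathy), no deaths
toy_chain_params <- function(p01 = 0.08, p12 = 0.05) {
  p <- inert_params()
  tr <- p$transitions
  tr$prob[tr$from == "renal_normal" & tr$to == "microalbuminuria"] <- p01
  tr$prob[tr$from == "microalbuminuria" & tr$to == "nephropathy"] <- p12
  p$transitions <- tr
  p
}

# a life table with no background mortality below the absorbing cap
no_mortality_life_table <- function() {
  lt <- generate_life_table()
  lt$q[lt$age < 99] <- 0
  lt
}

one_case_cohort <- function(age = 52, sex = "male", hypertensive = TRUE,
                            tau0 = 6, detected = NULL, mass = 1) {
  df <- data.frame(age = age, sex = sex, hypertensive = hypertensive,
                   diabetes = "undiagnosed", onset_years = tau0,
                   p_smoking = 0, p_hchol = 0, mass = mass)
  if (!is.null(detected)) df$detected <- detected
  structure(df, class = c("dm_cohort", "data.frame"),
            size = mass, mode = "expected")
}

# mass-conservation check over a trajectory: for every stratum,
# initial mass = alive at end + all deaths along the way, and each
# cycle's alive equals the previous alive minus that cycle's deaths
max_conservation_error <- function(traj) {
  strata <- attr(traj, "strata")
  worst <- 0
  for (id in unique(traj$stratum_id)) {
    g <- traj[traj$stratum_id == id, ]
    g <- g[order(g$cycle), ]
    prev <- strata$mass[strata$stratum_id == id]
    for (k in seq_len(nrow(g))) {
      worst <- max(worst, abs(prev - g$d_total[k] - g$alive[k]))
      prev <- g$alive[k]
    }
  }
  worst
}
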