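# Synthetic stand-ins for the national inputs the analysis draws on:
# demographic structure and all-cause mortality, risk-factor prevalence
# surfaces, and diabetes incidence inferred from prevalence.

#' Generate a synthetic Gompertz life table
#'
#' Produces annual all-cause mortality probabilities
#' `q(a) = 1 - exp(-level * exp(slope * a))` per sex for ages 40 to 99,
#' a standard Gompertz adult-mortality law. The terminal age is an
#' absorbing cap: `q(99) = 1`. The defaults are calibrated to plausible
#' early-2000s Brazilian adult mortality levels (around 0.4%/yr for men
#' and 0.2%/yr for women at 40, near 10%/yr at 80); they are a synthetic
#' stand-in for a national period life table, not survey data.
#'
#' @param knobs per-sex Gompertz parameters:
#'   `list(female = list(level, slope), male = list(level, slope))`,
#'   `level` the hazard scale and `slope` (> 0) the log-hazard slope per
#'   year of age
#' @param ages integer ages to tabulate (default 40:99)
#' @return data.frame with columns `age`, `sex` (`"female"`/`"male"`),
#'   `q` (annual death probability), of class `dm_life_table`
#' @export
generate_life_table <- function(knobs = list(
                                  female = list(level = 6.5e-5, slope = 0.090),
                                  male = list(level = 1.3e-4, slope = 0.085)),
                                ages = 40:99) {
  out <- do.call(rbind, lapply(names(knobs), function(sx) {
    k <- knobs[[sx]]
    if (!is.numeric(k$slope) || k$slope <= 0) {
      stop("life table slope for ", sx, " must be > 0")
    }
    if (!is.numeric(k$level) || k$level < 0) {
      stop("life table level for ", sx, " must be >= 0")
    }
    q <- 1 - exp(-k$level * exp(k$slope * ages))
    q[ages >= max(ages)] <- 1  # absorbing cap at the terminal age
    data.frame(age = ages, sex = sx, q = pmin(q, 1))
  }))
  class(out) <- c("dm_life_table", "data.frame")
  out
}

life_table_q <- function(life_table, age, sex) {
  a <- min(max(age, min(life_table$age)), max(life_table$age))
  life_table$q[life_table$age == a & life_table$sex == sex][1]
}

# ---- prevalence surface ----------------------------------------------------

#' Risk-factor and undiagnosed-diabetes prevalence surface, Brazil ~2001
#'
#' The age/sex prevalence inputs of the base case: undiagnosed diabetes
#' (5-year bands from 40), smoking, hypertension and hypercholesterolemia
#' (coarser survey bands; hypercholesterolemia is reported for both sexes
#' combined). Bands are mapped onto model ages by step interpolation; the
#' hypertension band starting at 35 covers model ages 40-44.
#'
#' @return data.frame with columns `condition`, `sex` (`"female"`,
#'   `"male"` or `"all"`), `age_lo`, `age_hi`, `prev` (fraction)
#' @export
brazil_prevalence_surface <- function() {
  band <- function(condition, sex, lo, hi, pct) {
    data.frame(condition = condition, sex = sex, age_lo = lo, age_hi = hi,
               prev = pct / 100)
  }
  rbind(
    band("undiagnosed_diabetes", "female",
         c(40, 45, 50, 55, 60, 65, 70, 75), c(44, 49, 54, 59, 64, 69, 74, 99),
         c(1.77, 2.63, 3.56, 4.09, 4.57, 4.53, 4.62, 4.79)),
    band("undiagnosed_diabetes", "male",
         c(40, 45, 50, 55, 60, 65, 70, 75), c(44, 49, 54, 59, 64, 69, 74, 99),
         c(2.31, 3.23, 4.30, 5.06, 4.61, 4.97, 4.75, 4.53)),
    band("smoking", "female", c(18, 35, 50), c(34, 49, 99),
         c(11.8, 20.8, 11.4)),
    band("smoking", "male", c(18, 35, 50), c(34, 49, 99),
         c(19.2, 25.5, 24.2)),
    band("hypertension", "female", c(35, 45, 55, 65, 75), c(44, 54, 64, 74, 99),
         c(17.9, 31.0, 47.2, 57.5, 52.0)),
    band("hypertension", "male", c(35, 45, 55, 65, 75), c(44, 54, 64, 74, 99),
         c(15.3, 28.7, 37.7, 52.8, 46.5)),
    band("hypercholesterolemia", "all", c(0, 25, 35, 45, 55),
         c(24, 34, 44, 54, 99), c(8.0, 10.9, 20.9, 28.8, 32.3))
  )
}

#' Look up a prevalence surface value by age (step interpolation)
#'
#' @param surface a prevalence surface data.frame (see
#'   [brazil_prevalence_surface()])
#' @param condition condition name
#' @param age integer age
#' @param sex `"female"` or `"male"`; conditions tabulated for `"all"`
#'   match either
#' @return prevalence fraction in \[0, 1\]
#' @export
surface_value <- function(surface, condition, age, sex) {
  g <- surface[surface$condition == condition &
                 (surface$sex == sex | surface$sex == "all"), , drop = FALSE]
  if (!nrow(g)) stop("no surface entries for condition '", condition, "'")
  a <- min(max(age, min(g$age_lo)), max(g$age_hi))
  g$prev[g$age_lo <= a & g$age_hi >= a][1]
}

#' Default synthetic age/sex structure for the 40+ cohort
#'
#' Five-year entry bands from 40-44 to 75-79 with population weights
#' declining geometrically with age (a stand-in for a developing-country
#' adult age pyramid) and a 52/48 female/male split.
#'
#' @return list with `age_bands` (data.frame `age_lo`, `age_hi`,
#'   `weight`, weights summing to 1) and `sex_share` (named fractions)
#' @export
default_age_structure <- function() {
  lo <- seq(40, 75, by = 5)
  w <- exp(-0.035 * (lo - 40))
  list(
    age_bands = data.frame(age_lo = lo, age_hi = lo + 4, weight = w / sum(w)),
    sex_share = c(female = 0.52, male = 0.48)
  )
}

# ---- cohort ----------------------------------------------------------------

new_dm_cohort <- function(df, size, mode, seed = NULL) {
  structure(df, class = c("dm_cohort", "data.frame"),
            size = size, mode = mode, seed = seed)
}

#' Generate the screening-eligible cohort
#'
#' Builds a stratified cohort of adults aged 40 and over with no known
#' diabetes, carrying per-stratum masses over entry age (band midpoints),
#' sex, hypertension status and diabetes status (`"none"` or
#' `"undiagnosed"`). Undiagnosed cases carry a time-since-onset
#' distribution: by default uniform over completed years
#' `0 .. lead_time_years - 1`, so the average undetected case is midway
#' through its pre-diagnosis window; alternatively a single assumed
#' onset time (`onset_years_at_screening`), the convention of the
#' screening module, where detected cases are diagnosed at screening
#' having had diabetes for `lead_time_years - detection_benefit` years.
#' Smoking and hypercholesterolemia prevalences are carried as stratum
#' fractions (they feed the stroke risk equation).
#'
#' In `"expected"` mode stratum masses are the exact prevalence products;
#' in `"sampled"` mode individuals are drawn multinomially with the given
#' seed (reproducible). Either way the masses sum exactly to `size`.
#'
#' Undiagnosed-diabetes prevalence may be made hypertension-conditional
#' through `dm_ht_prevalence_ratio`, the ratio of prevalence in
#' hypertensive vs non-hypertensive persons of the same age and sex; the
#' age/sex margins of the surface are preserved exactly.
#'
#' @param surface prevalence surface (see [brazil_prevalence_surface()])
#' @param size cohort size (> 0)
#' @param mode `"expected"` or `"sampled"`
#' @param seed RNG seed for sampled mode
#' @param structure age/sex structure (see [default_age_structure()])
#' @param dm_ht_prevalence_ratio relative prevalence of undiagnosed
#'   diabetes given hypertension (default 1.6, a documented assumption;
#'   1 makes the conditions independent)
#' @param lead_time_years onset-to-clinical-diagnosis window (years)
#' @param onset_years_at_screening `NULL` for the uniform onset mix, or
#'   a single completed-years value in `0 .. lead_time_years` assumed
#'   for every undiagnosed case
#' @return a `dm_cohort` data.frame with columns `age`, `sex`,
#'   `hypertensive`, `diabetes`, `onset_years`, `p_smoking`, `p_hchol`,
#'   `mass`
#' @export
generate_cohort <- function(surface, size, mode = c("expected", "sampled"),
                            seed = 1L, structure = default_age_structure(),
                            dm_ht_prevalence_ratio = 1.6,
                            lead_time_years = 10,
                            onset_years_at_screening = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(size) || size <= 0) stop("cohort size must be > 0")
  taus <- if (is.null(onset_years_at_screening)) {
    seq_len(lead_time_years) - 1L
  } else {
    stopifnot(onset_years_at_screening >= 0,
              onset_years_at_screening <= lead_time_years)
    as.integer(onset_years_at_screening)
  }
  rows <- list()
  for (bi in seq_len(nrow(structure$age_bands))) {
    age <- structure$age_bands$age_lo[bi] + 2L  # band midpoint entry age
    for (sx in names(structure$sex_share)) {
      base <- size * structure$age_bands$weight[bi] * structure$sex_share[[sx]]
      h <- surface_value(surface, "hypertension", age, sx)
      p <- surface_value(surface, "undiagnosed_diabetes", age, sx)
      r <- dm_ht_prevalence_ratio
      denom <- 1 + h * (r - 1)
      p_by_ht <- c(`TRUE` = p * r / denom, `FALSE` = p / denom)
      ps <- surface_value(surface, "smoking", age, sx)
      pc <- surface_value(surface, "hypercholesterolemia", age, sx)
      for (ht in c(TRUE, FALSE)) {
        m <- base * if (ht) h else (1 - h)
        pg <- min(p_by_ht[[as.character(ht)]], 1)
        rows[[length(rows) + 1L]] <- data.frame(
          age = age, sex = sx, hypertensive = ht,
          diabetes = c("none", rep("undiagnosed", length(taus))),
          onset_years = c(NA_integer_, taus),
          p_smoking = ps, p_hchol = pc,
          mass = c(m * (1 - pg), rep(m * pg / length(taus), length(taus))))
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (mode == "sampled") {
    set.seed(seed)
    df$mass <- as.numeric(stats::rmultinom(1, size = round(size),
                                           prob = df$mass / sum(df$mass)))
  }
  new_dm_cohort(df, size = size, mode = mode,
                seed = if (mode == "sampled") seed)
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat("<dm_cohort> ", nrow(x), " strata, total mass ",
      format(sum(x$mass)), " (", attr(x, "mode"), " mode)\n", sep = "")
  und <- sum(x$mass[x$diabetes == "undiagnosed"])
  cat("  undiagnosed diabetes mass: ", format(und), " (",
      sprintf("%.2f%%", 100 * und / sum(x$mass)), ")\n", sep = "")
  invisible(x)
}

# ---- incidence from prevalence (discrete illness-death model) --------------

#' Project prevalence forward through the illness-death recurrence
#'
#' Forward simulator of the discrete three-state (well, ill, dead)
#' illness-death model: in each one-year step, incidence `i(a)` moves
#' well mass to ill, remission `r` moves ill mass back, then mortality
#' removes mass with survival `(1 - q)` for the well and `(1 - q)^RR`
#' for the ill (a proportional-hazards excess mortality). Prevalence is
#' the ill share among survivors.
#'
#' @param ages integer ages, length n
#' @param incidence annual incidence per age step, length n - 1
#' @param relative_mortality hazard ratio for the ill (>= 1)
#' @param remission annual remission probability (default 0)
#' @param q background annual mortality per age step (length n - 1 or a
#'   scalar; default 0)
#' @param p0 prevalence at `ages[1]` (default 0)
#' @return prevalence vector along `ages`
#' @export
project_prevalence <- function(ages, incidence, relative_mortality = 1,
                               remission = 0, q = 0, p0 = 0) {
  n <- length(ages)
  stopifnot(length(incidence) == n - 1)
  q <- rep_len(q, n - 1)
  P <- numeric(n)
  P[1] <- p0
  for (k in seq_len(n - 1)) {
    D1 <- P[k] + incidence[k] * (1 - P[k]) - remission * P[k]
    s_w <- 1 - q[k]
    s_d <- (1 - q[k])^relative_mortality
    denom <- D1 * s_d + (1 - D1) * s_w
    P[k + 1] <- if (denom > 0) D1 * s_d / denom else 1
  }
  P
}

#' Estimate incidence from prevalence (illness-death inversion)
#'
#' Inverts the discrete illness-death recurrence of
#' [project_prevalence()] step by step: given prevalence at consecutive
#' ages, background mortality and the relative mortality of the ill, it
#' solves each one-year step for the incidence that reproduces the
#' observed prevalence change. This is the same bookkeeping national
#' burden-of-disease tools use to derive incidence when only prevalence
#' surveys exist. Forward-simulating the recurrence with the returned
#' incidence reproduces the input prevalence to numerical precision.
#'
#' @param ages integer ages, length n (consecutive steps)
#' @param prevalence prevalence at each age, in \[0, 1\]
#' @param relative_mortality hazard ratio for the ill (>= 1)
#' @param remission annual remission probability (default 0)
#' @param q background annual mortality per step (scalar or length n - 1)
#' @return data.frame with columns `age` (step start) and `incidence`
#' @export
estimate_incidence_from_prevalence <- function(ages, prevalence,
                                               relative_mortality = 1,
                                               remission = 0, q = 0) {
  n <- length(ages)
  stopifnot(length(prevalence) == n)
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence must be in [0, 1]")
  }
  if (relative_mortality < 1) stop("relative_mortality must be >= 1")
  q <- rep_len(q, n - 1)
  inc <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    P <- prevalence[k]
    Pn <- prevalence[k + 1]
    s_w <- 1 - q[k]
    s_d <- (1 - q[k])^relative_mortality
    D1 <- Pn * s_w / (s_d * (1 - Pn) + Pn * s_w)
    i <- if (P >= 1) 0 else (D1 - P * (1 - remission)) / (1 - P)
    if (i < -1e-12) {
      stop("implied incidence is negative at age step ", ages[k], " -> ",
           ages[k + 1], " (prevalence falls faster than mortality explains)")
    }
    inc[k] <- max(i, 0)
  }
  data.frame(age = ages[-n], incidence = inc)
}

#' Export a cohort (or life table) to CSV
#'
#' Plain CSV with the documented column order; generation metadata
#' (size, mode, seed) is recorded in a `#`-prefixed header line.
#'
#' @param x a `dm_cohort` or `dm_life_table`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- if (inherits(x, "dm_cohort")) {
    sprintf("# dm_cohort size=%s mode=%s seed=%s", attr(x, "size"),
            attr(x, "mode"), attr(x, "seed") %||% "NA")
  } else {
    "# dm_life_table"
  }
  writeLines(meta, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#'
#' @param path file path
#' @return a `dm_cohort` data.frame
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new_dm_cohort(df, size = sum(df$mass), mode = "imported")
}
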