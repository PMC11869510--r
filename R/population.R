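#' Generate the synthetic female population
#'
#' Women are assigned a birth year (cohort sizes growing geometrically at the
#' configured annual rate), a uniform birthday within the year, a risk class
#' (high with probability 25%), an other-cause death age drawn from the life
#' table, and a constant sampling weight `represented_women / n_women`.
#'
#' Birth years span `start_year - 74` to `end_year - 40`, so every woman who is
#' ever screening-aged (40--74) during the reporting window is representable;
#' women already older than 74 at the window start contribute no screening
#' outcomes and are excluded. The population is closed (no migration).
#'
#' @param config A [sim_config()]; its `seed` is NOT applied here -- call
#'   `set.seed()` upstream or use [run_simulation()], which manages one stream
#'   for the whole run.
#' @param high_risk_fraction Population share at high risk.
#' @return `data.table` (id, birth_year, birth_date, risk_class,
#'   other_cause_death_age, weight), keyed by id.
#' @export
generate_population <- function(config, high_risk_fraction = 0.25) {
  n <- config$n_women
  if (is.null(n) || n < 1) stop("n_women must be >= 1")
  years <- seq.int(config$start_year - 74L, config$end_year - 40L)
  prob <- (1 + config$growth_rate)^(years - years[1])
  birth_year <- sample(years, n, replace = TRUE, prob = prob / sum(prob))
  pop <- data.table(
    id = seq_len(n),
    birth_year = birth_year,
    birth_date = birth_year + runif(n),
    risk_class = ifelse(runif(n) < high_risk_fraction, "high", "average"),
    other_cause_death_age = sample_other_cause_death_age(n, config$life_table),
    weight = config$represented_women / n
  )
  setkey(pop, id)
  pop[]
}

#' Sample other-cause death ages from a life table
#'
#' Inverse-transform sampling of the discrete death-age distribution implied by
#' annual death probabilities `qx`: `P(death at age a) = S(a) * q(a)` with
#' `S(a)` the survival to exact age `a`. The terminal `q(119) = 1` caps every
#' death age at 119.
#'
#' @param n Number of draws.
#' @param life_table `data.frame(age = 0:119, qx)`.
#' @param u Optional uniforms (for reproducible coupling).
#' @return Numeric vector of integer-valued death ages, all `<= 119`.
#' @export
sample_other_cause_death_age <- function(n, life_table = default_life_table(),
                                         u = runif(n)) {
  validate_life_table(life_table)
  qx <- life_table$qx
  S <- cumprod(c(1, 1 - qx[-length(qx)]))     # survival to exact age a
  p <- S * qx                                  # death during year of age a
  life_table$age[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
}

#' Life-table survival curve
#'
#' @param life_table `data.frame(age, qx)`.
#' @return `data.frame(age, survival)` with survival to exact age.
#' @export
life_table_survival <- function(life_table = default_life_table()) {
  data.frame(age = life_table$age,
             survival = cumprod(c(1, 1 - life_table$qx[-nrow(life_table)])))
}
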