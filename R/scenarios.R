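SCENARIO_NAMES <- c("SQ", "A40", "B40", "A45", "B45")

#' Define a screening policy
#'
#' The five policies share a core band (biennial screening at ages 50--74,
#' offers anchored at age 50) and a baseline of ~25% annual uptake at ages
#' 40--49 carried by high-risk women in every scenario and calendar year.
#' The four revisions add an organized young-age band for enrolled average-risk
#' women starting 2024-01-01: `A40`/`B40` cover ages 40--49 at a 1-/2-year
#' interval, `A45`/`B45` cover ages 45--49. `SQ` has no young band beyond the
#' baseline and ignores `target_participation`.
#'
#' @param name One of `"SQ"`, `"A40"`, `"B40"`, `"A45"`, `"B45"`.
#' @param target_participation Overall target participation among women aged
#'   40--49 (high- plus average-risk combined), in (0, 1].
#' @return List of class `"scenario"` with the band definition.
#' @export
#' @examples
#' build_scenario("A40", 0.50)
build_scenario <- function(name, target_participation = 0.50) {
  if (length(name) != 1L || !name %in% SCENARIO_NAMES)
    stop("config error at `name`: unknown scenario ", paste(name, collapse = ","),
         "; expected one of ", paste(SCENARIO_NAMES, collapse = ", "))
  if (target_participation <= 0 || target_participation > 1)
    stop("config error at `target_participation`: must be in (0, 1]")
  young <- switch(name,
    SQ  = NULL,
    A40 = list(low = 40L, high = 49L, interval = 1L),
    B40 = list(low = 40L, high = 49L, interval = 2L),
    A45 = list(low = 45L, high = 49L, interval = 1L),
    B45 = list(low = 45L, high = 49L, interval = 2L)
  )
  structure(list(
    name = name,
    young_band = young,
    core_band = list(low = 50L, high = 74L, interval = 2L),
    policy_start = 2024.0,  # calendar date as fractional year (2024-01-01)
    target_participation = if (name == "SQ") NA_real_ else target_participation
  ), class = "scenario")
}

#' Participation model
#'
#' The population is 25% high risk; high-risk women already screen annually at
#' ages 40--49 with a 100% re-screen rate, in every scenario. A target overall
#' participation `t` among women aged 40--49 is therefore met by enrolling
#' average-risk women with probability `p_avg = (t - 0.25) / 0.75`, clamped to
#' `[0, 1]`; at `t = 0.25` the young-age program adds nothing beyond the status
#' quo. The re-screen rate (probability of attending any offer after the first
#' offer of a program) is 1.00 for high-risk and 0.63 for average-risk women.
#'
#' @param target_participation Overall target in (0, 1].
#' @param high_risk_fraction Population share at high risk.
#' @param rescreen_high,rescreen_avg Re-screen rates by risk class.
#' @return List of class `"participation_model"` including the derived
#'   `average_risk_enrollment`.
#' @export
participation_model <- function(target_participation = 0.50,
                                high_risk_fraction = 0.25,
                                rescreen_high = 1.00, rescreen_avg = 0.63) {
  p_avg <- (target_participation - high_risk_fraction) / (1 - high_risk_fraction)
  structure(list(
    high_risk_fraction = high_risk_fraction,
    target_participation = target_participation,
    average_risk_enrollment = min(1, max(0, p_avg)),
    rescreen_high = rescreen_high, rescreen_avg = rescreen_avg,
    core_band_enrollment = 1.0
  ), class = "participation_model")
}

#' Build the offered-screen table for a set of women under one scenario
#'
#' Screens are offered on birthday anniversaries (age attainment). Offers
#' comprise: (a) the annual baseline at ages 40--49 for high-risk women in all
#' scenarios and years; (b) the scenario's young band for enrolled average-risk
#' women, from the first band-eligible birthday on or after the 2024-01-01
#' policy start, at the scenario interval (biennial phases anchor at that first
#' eligible offer); (c) the core band, even ages 50--74, for every woman.
#' Offers are restricted to calendar window 2015--2051 and to ages before the
#' woman's other-cause death.
#'
#' @param women `data.table` with columns `id`, `birth_date` (fractional year),
#'   `risk_class` (`"high"`/`"average"`), `other_cause_death_age`, and
#'   `enrolled` (logical; young-program membership, ignored for `SQ`).
#' @param scenario A [build_scenario()] object.
#' @param window Calendar-year limits as `c(first, last)`.
#' @return `data.table` (id, program, age, date, offer_index) sorted by id, age;
#'   `offer_index` counts a woman's offers in age order.
#' @export
offer_schedule <- function(women, scenario, window = c(2015L, 2051L)) {
  stopifnot(inherits(scenario, "scenario"))
  w <- as.data.table(women)
  offers <- list()

  # (a) baseline annual 40-49, high-risk women, all years
  hi <- w[risk_class == "high", .(id, birth_date, other_cause_death_age)]
  if (nrow(hi))
    offers$baseline <- hi[, .(age = 40:49, program = "young"),
                          by = .(id, birth_date, other_cause_death_age)]

  # (b) scenario young band, enrolled average-risk women, from policy start
  yb <- scenario$young_band
  if (!is.null(yb)) {
    av <- w[risk_class == "average" & enrolled == TRUE,
            .(id, birth_date, other_cause_death_age)]
    if (nrow(av)) {
      av[, first_age := pmax(yb$low, as.integer(ceiling(scenario$policy_start - birth_date)))]
      av <- av[first_age <= yb$high]
      if (nrow(av))
        offers$young <- av[, .(age = seq.int(first_age, yb$high, by = yb$interval),
                               program = "young"),
                           by = .(id, birth_date, other_cause_death_age)]
    }
  }

  # (c) core band, all women, biennial anchored at 50
  cb <- scenario$core_band
  offers$core <- w[, .(id, birth_date, other_cause_death_age)][
    , .(age = seq.int(cb$low, cb$high, by = cb$interval), program = "core"),
    by = .(id, birth_date, other_cause_death_age)]

  out <- rbindlist(offers, use.names = TRUE)
  out[, date := birth_date + age]
  out <- out[date >= window[1] & date < window[2] + 1 & age < other_cause_death_age]
  setorder(out, id, age)
  out[, offer_index := seq_len(.N), by = id]
  out[, c("birth_date", "other_cause_death_age") := NULL]
  out[]
}

#' Does a woman attend an offered screen?
#'
#' The first offer of each program (young band, core band) is attended with
#' probability 1; every subsequent offer is attended independently with the
#' risk-class re-screen rate.
#'
#' @param risk_class `"high"` or `"average"` (vectorized).
#' @param first_of_program Logical; is this the woman's first offer within the
#'   offering program?
#' @param u Uniform(0,1) draw per offer (supply to couple scenarios; defaults
#'   to fresh draws).
#' @param pm A [participation_model()].
#' @return Logical vector of attendance.
#' @export
attends <- function(risk_class, first_of_program, u = runif(length(risk_class)),
                    pm = participation_model()) {
  rate <- ifelse(risk_class == "high", pm$rescreen_high, pm$rescreen_avg)
  first_of_program | (u < rate)
}

#' Mark attended offers on an offer table
#'
#' Applies [attends()] using age-keyed uniform draws so that common random
#' numbers couple scenarios: the same woman facing an offer at the same age
#' sees the same draw in every scenario.
#'
#' @param offers Output of [offer_schedule()].
#' @param women Population table (for `risk_class`).
#' @param u_attend Matrix `[n_women, ages 40..74]` of uniforms, rows indexed by `id`.
#' @param pm A [participation_model()].
#' @return `offers` with logical column `attended` and, on attended rows only,
#'   `is_first_screen` (first attended screen of the woman's life).
#' @keywords internal
mark_attendance <- function(offers, women, u_attend, pm) {
  off <- copy(offers)
  off[women, risk_class := i.risk_class, on = "id"]
  off[, first_of_program := seq_len(.N) == 1L, by = .(id, program)]
  u <- u_attend[cbind(off$id, off$age - 39L)]
  off[, attended := attends(risk_class, first_of_program, u, pm)]
  off[, first_of_program := NULL]
  off[attended == TRUE, is_first_screen := seq_len(.N) == 1L, by = id]
  off[]
}
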