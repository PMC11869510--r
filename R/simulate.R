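TALLY_COUNT_COLS <- c("screens", "recalls", "recalls_no_cancer", "biopsies",
                      "negative_biopsies", "invasive_dx", "screen_detected_dx",
                      "stage_0", "stage_I", "stage_II", "stage_III", "stage_IV",
                      "bc_deaths", "new_women_screened")

#' Run the microsimulation for a set of coupled scenarios
#'
#' One random stream, seeded once, draws the population, every latent disease
#' history, the age-keyed screening uniforms and the per-woman survival
#' quantile BEFORE the scenario loop, so all scenarios in a run (and any subset
#' of them) see identical women, identical histories and identical draws at the
#' same (woman, age): every between-scenario difference is screening-induced
#' (common random numbers). The run is byte-reproducible given `seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_run"`: `tallies` (one row per scenario-year with
#'   weighted counts and `women_screened_to_date`), `screen_years` (unique
#'   woman-year screen records per scenario, for window-unique counts),
#'   `diagnoses` per scenario, `events` per scenario when `keep_events`,
#'   `population`, `histories`, `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_women
  ages <- 40:74

  pop <- generate_population(config)
  hist <- sample_tumor_history(pop, config$nh)

  draws <- list(
    u_enroll = runif(n),
    u_attend = matrix(runif(n * length(ages)), n, length(ages)),
    u_screen = matrix(runif(n * length(ages)), n, length(ages)),
    u_biopsy_ref = matrix(runif(n * length(ages)), n, length(ages)),
    u_biopsy_pos = matrix(runif(n * length(ages)), n, length(ages)),
    u_surv = runif(n)
  )

  pm <- participation_model(config$target_participation)
  window <- c(config$start_year, config$end_year)

  tallies <- list(); screen_years <- list(); diagnoses <- list(); events <- list()
  for (nm in config$scenarios) {
    sc <- simulate_scenario(nm, pop, hist, draws, pm, config)
    tallies[[nm]] <- sc$tally
    screen_years[[nm]] <- sc$screen_years
    diagnoses[[nm]] <- sc$diagnoses
    if (config$keep_events) events[[nm]] <- sc$events
  }

  structure(list(
    tallies = rbindlist(tallies),
    screen_years = rbindlist(screen_years),
    diagnoses = diagnoses,
    events = if (config$keep_events) events,
    population = pop, histories = hist, config = config
  ), class = "sim_run")
}

#' Simulate one scenario against fixed population, histories and draws
#' @keywords internal
simulate_scenario <- function(name, pop, hist, draws, pm, config) {
  scen <- build_scenario(name, config$target_participation)
  window <- c(config$start_year, config$end_year)

  women <- pop[, .(id, birth_date, risk_class, other_cause_death_age)]
  women[, enrolled := risk_class == "average" &
          draws$u_enroll[id] < pm$average_risk_enrollment]

  offers <- offer_schedule(women, scen, window)
  offers <- mark_attendance(offers, pop, draws$u_attend, pm)
  screens <- offers[attended == TRUE]
  screens <- perform_screen(screens, hist, config$perf, draws, config$nh)

  res <- resolve_diagnosis(screens, hist, pop, config$nh)
  ev <- res$events
  dx <- res$diagnoses

  bc_age <- sample_bc_death_age(dx, draws$u_surv[dx$id], config$surv)
  dx[, bc_death_age := bc_age]
  death <- adjudicate_death(dx$bc_death_age, pop[.(dx$id), other_cause_death_age])
  dx[, `:=`(death_age = death$death_age, cause = death$cause)]

  tally <- build_tally(name, ev, dx, pop, window)
  list(
    tally = tally,
    screen_years = unique(ev[, .(scenario = name, id, year = as.integer(floor(date)))]),
    diagnoses = dx,
    events = ev
  )
}

#' Assemble the annual tally for one scenario
#'
#' Counts are scaled by the constant per-woman weight; the calendar year of an
#' event is the year containing its (fractional-year) date.
#'
#' @keywords internal
build_tally <- function(name, events, diagnoses, pop, window) {
  years <- seq.int(window[1], window[2])
  weight <- pop$weight[1]
  grid <- data.table(scenario = name, year = years)

  ev <- copy(events)[, year := as.integer(floor(date))]
  scr <- ev[, .(
    screens = .N,
    recalls = sum(recall),
    recalls_no_cancer = sum(recall & !led_to_diagnosis),
    biopsies = sum(biopsy),
    negative_biopsies = sum(biopsy & !biopsy_positive)
  ), by = year]
  first_scr <- ev[, .(first_year = min(year)), by = id][, .(new_women_screened = .N),
                                                        by = .(year = first_year)]

  dxx <- copy(diagnoses)[, dx_year := as.integer(floor(dx_date))]
  dxx <- dxx[dx_year >= window[1] & dx_year <= window[2]]
  dxt <- dxx[, .(
    invasive_dx = sum(stage != "0"),
    screen_detected_dx = sum(detection_mode == "screen"),
    stage_0 = sum(stage == "0"), stage_I = sum(stage == "I"),
    stage_II = sum(stage == "II"), stage_III = sum(stage == "III"),
    stage_IV = sum(stage == "IV")
  ), by = .(year = dx_year)]

  deaths <- diagnoses[cause == "breast_cancer",
                      .(id, year = as.integer(floor(dx_date - dx_age + death_age)))]
  deaths <- deaths[year >= window[1] & year <= window[2],
                   .(bc_deaths = .N), by = year]

  tal <- Reduce(function(a, b) merge(a, b, by = "year", all.x = TRUE),
                list(grid[, .(year)], scr, dxt, deaths, first_scr))
  for (cc in TALLY_COUNT_COLS) {
    if (!cc %in% names(tal)) tal[, (cc) := 0L]
    set(tal, which(is.na(tal[[cc]])), cc, 0L)
    tal[, (cc) := as.numeric(get(cc)) * weight]
  }
  tal[, scenario := name]
  tal[, women_screened_to_date := cumsum(new_women_screened)]
  setcolorder(tal, c("scenario", "year", TALLY_COUNT_COLS, "women_screened_to_date"))
  setorder(tal, year)
  tal[]
}

#' Unique women screened within a calendar window
#'
#' Table 2's "women screened" counts distinct women with at least one screen in
#' the window (the published A40 and B40 values coincide, which only a
#' unique-women reading produces).
#'
#' @param run A [run_simulation()] result.
#' @param window `c(first_year, last_year)`.
#' @return `data.table(scenario, women_screened)` (weighted).
#' @export
women_screened <- function(run, window = c(2024L, 2043L)) {
  w <- run$population$weight[1]
  run$screen_years[year >= window[1] & year <= window[2],
                   .(women_screened = uniqueN(id) * w), by = scenario]
}

#' Write tally CSVs deterministically
#'
#' @param tallies Tally table from a run.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tallies <- function(tallies, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  fwrite(tallies, path, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read a tally CSV
#' @param path CSV written by [write_tallies()].
#' @return `data.table` of tallies.
#' @export
read_tallies <- function(path) fread(path)
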