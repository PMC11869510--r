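OUTCOME_COLS <- c("screens", "recalls_no_cancer", "biopsies", "negative_biopsies",
                  "invasive_dx", "screen_detected_dx", "bc_deaths")
STAGE_LEVELS <- c("0", "I", "II", "III", "IV")

#' Cumulative totals over a window of calendar years
#'
#' Exact sums of the annual tallies over years `window[1]..window[2]`
#' inclusive, per scenario.
#'
#' @param tallies Tally table (columns `scenario`, `year`, outcome counts).
#' @param window `c(first_year, last_year)`.
#' @return One row per scenario with summed outcome and stage columns.
#' @export
cumulate <- function(tallies, window = c(2024L, 2043L)) {
  tl <- as.data.table(tallies)
  if (window[1] > window[2]) stop("window must satisfy first <= last")
  have <- tl[, sort(unique(year))]
  need <- seq.int(window[1], window[2])
  if (!all(need %in% have))
    stop("window ", window[1], "-", window[2], " outside tally coverage (",
         min(have), "-", max(have), ")")
  cols <- intersect(c(OUTCOME_COLS, "recalls", paste0("stage_", c("0", "I", "II", "III", "IV")),
                      "new_women_screened"), names(tl))
  tl[year >= window[1] & year <= window[2],
     lapply(.SD, sum), by = scenario, .SDcols = cols]
}

#' Compare an alternate scenario against the referent
#'
#' For every outcome: `absolute_difference = alt - ref` and
#' `relative_change_pct = 100 * (alt - ref) / ref` (increases positive, the
#' sign convention of the published tables). Deaths averted is reported as the
#' positive quantity `ref_bc_deaths - alt_bc_deaths`. When a referent total is
#' zero the relative change is undefined: it is returned `NA` and flagged,
#' with the absolute difference still reported.
#'
#' @param ref_totals,alt_totals One-row totals (e.g. rows of [cumulate()] or of
#'   the packaged cumulative table) with the outcome columns.
#' @return `data.table` of class `"comparison_report"` (one row per outcome)
#'   with attributes `referent`, `alternate`, `deaths_averted`,
#'   `efficiency_point`.
#' @export
compare_scenarios <- function(ref_totals, alt_totals) {
  ref <- as.data.table(ref_totals); alt <- as.data.table(alt_totals)
  stopifnot(nrow(ref) == 1L, nrow(alt) == 1L)
  cols <- intersect(intersect(names(ref), names(alt)),
                    c(OUTCOME_COLS, paste0("stage_", STAGE_LEVELS)))
  if (!"screens" %in% cols || ref$screens <= 0)
    stop("referent screens total must be positive")
  out <- data.table(
    outcome = cols,
    ref_total = as.numeric(unlist(ref[, cols, with = FALSE])),
    alt_total = as.numeric(unlist(alt[, cols, with = FALSE]))
  )
  out[, absolute_difference := alt_total - ref_total]
  out[, relative_change_pct := fifelse(ref_total == 0, NA_real_,
                                       100 * absolute_difference / ref_total)]
  out[, undefined_relative := ref_total == 0]
  setattr(out, "referent", if (!is.null(ref$scenario)) ref$scenario else NA_character_)
  setattr(out, "alternate", if (!is.null(alt$scenario)) alt$scenario else NA_character_)
  setattr(out, "deaths_averted",
          as.numeric(ref$bc_deaths - alt$bc_deaths))
  setattr(out, "efficiency_point",
          c(additional_screens = as.numeric(alt$screens - ref$screens),
            deaths_averted = as.numeric(ref$bc_deaths - alt$bc_deaths)))
  setattr(out, "class", c("comparison_report", class(out)))
  out[]
}

#' Outcome rate per 100,000 screens
#'
#' `100000 * outcome_total / screens_total`, each scenario's own screens in the
#' denominator. Rounding is presentation-only; this returns the unrounded rate.
#'
#' @param outcome_total,screens_total Totals (vectorized).
#' @return Numeric rates.
#' @export
rate_per_100k <- function(outcome_total, screens_total) {
  if (any(screens_total <= 0)) stop("screens_total must be positive")
  1e5 * outcome_total / screens_total
}

#' Rates per 100,000 screens for every scenario and outcome
#'
#' @param totals Output of [cumulate()] (or the packaged cumulative fixture).
#' @return Long `data.table(scenario, outcome, rate)`; outcomes exclude screens.
#' @export
rates_table <- function(totals) {
  tt <- as.data.table(totals)
  cols <- setdiff(intersect(OUTCOME_COLS, names(tt)), "screens")
  out <- melt(tt[, c("scenario", "screens", cols), with = FALSE],
              id.vars = c("scenario", "screens"), variable.name = "outcome",
              value.name = "total", variable.factor = FALSE)
  out[, rate := rate_per_100k(total, screens)]
  out[, c("scenario", "outcome", "rate", "total"), with = FALSE]
}

#' Stage distribution (counts and proportions) per scenario
#'
#' Proportions are percentages of all diagnoses (DCIS + invasive) in the
#' window; they sum to 100 up to rounding.
#'
#' @param totals Output of [cumulate()] with `stage_*` columns, or a long table
#'   `(scenario, stage, count)`.
#' @return `data.table(scenario, stage, count, proportion_pct)`.
#' @export
stage_table <- function(totals) {
  tt <- as.data.table(totals)
  if ("stage" %in% names(tt)) {
    long <- tt[, .(scenario, stage, count)]
  } else {
    long <- melt(tt[, c("scenario", paste0("stage_", STAGE_LEVELS)), with = FALSE],
                 id.vars = "scenario", variable.name = "stage", value.name = "count",
                 variable.factor = FALSE)
    long[, stage := sub("^stage_", "", stage)]
  }
  long[, stage := factor(stage, levels = STAGE_LEVELS)]
  long[, proportion_pct := 100 * count / sum(count), by = scenario]
  setorder(long, scenario, stage)
  long[]
}

#' Stage shift of an alternate scenario against the referent
#'
#' @param stages Long stage table (from [stage_table()] or the packaged stage
#'   fixture) covering both scenarios.
#' @param referent,alternate Scenario names.
#' @return `data.table(stage, ref_count, alt_count, difference, relative_change_pct)`.
#' @export
stage_shift <- function(stages, referent = "SQ", alternate) {
  st <- as.data.table(stages)
  ref <- st[scenario == referent, .(stage, ref_count = count)]
  alt <- st[scenario == alternate, .(stage, alt_count = count)]
  out <- merge(ref, alt, by = "stage", sort = FALSE)
  out[, difference := alt_count - ref_count]
  out[, relative_change_pct := 100 * difference / ref_count]
  out[]
}

#' Implementation-year change in outcomes
#'
#' Absolute and percent change of each outcome between two single calendar
#' years (the published comparison is 2023 to 2024, the first program year).
#'
#' @param tallies Tally table.
#' @param from_year,to_year Calendar years, both within coverage.
#' @return `data.table(scenario, outcome, from_value, to_value, change, change_pct)`.
#' @export
implementation_surge <- function(tallies, from_year = 2023L, to_year = 2024L) {
  tl <- as.data.table(tallies)
  if (!all(c(from_year, to_year) %in% tl$year))
    stop("both years must be within tally coverage")
  cols <- intersect(OUTCOME_COLS, names(tl))
  a <- melt(tl[year == from_year, c("scenario", cols), with = FALSE],
            id.vars = "scenario", variable.name = "outcome", value.name = "from_value",
            variable.factor = FALSE)
  b <- melt(tl[year == to_year, c("scenario", cols), with = FALSE],
            id.vars = "scenario", variable.name = "outcome", value.name = "to_value",
            variable.factor = FALSE)
  out <- merge(a, b, by = c("scenario", "outcome"), sort = FALSE)
  out[, change := to_value - from_value]
  out[, change_pct := fifelse(from_value == 0, NA_real_, 100 * change / from_value)]
  out[]
}

#' Deaths-averted efficiency frontier
#'
#' Points (additional screens, deaths averted) of each alternate against the
#' shared referent, sorted by additional screens, with the slope of each
#' consecutive segment (averted deaths per additional screen). Duplicate
#' x-positions make the slope undefined and are flagged.
#'
#' @param reports List of [compare_scenarios()] reports sharing the referent.
#' @return `data.table(alternate, additional_screens, deaths_averted, slope,
#'   undefined_slope)`; `slope` is `NA` for the first point.
#' @export
efficiency_frontier <- function(reports) {
  refs <- vapply(reports, attr, character(1), which = "referent")
  if (length(unique(refs)) != 1L)
    stop("all comparison reports must share the same referent")
  pts <- rbindlist(lapply(reports, function(r) {
    p <- attr(r, "efficiency_point")
    data.table(alternate = attr(r, "alternate"),
               additional_screens = p[["additional_screens"]],
               deaths_averted = p[["deaths_averted"]])
  }))
  setorder(pts, additional_screens)
  dx <- diff(pts$additional_screens)
  dy <- diff(pts$deaths_averted)
  pts[, slope := c(NA_real_, fifelse(dx == 0, NA_real_, dy / dx))]
  pts[, undefined_slope := c(FALSE, dx == 0)]
  pts[]
}

#' Full report over a set of scenario totals
#'
#' The single code path used for both simulated tallies and the packaged
#' cumulative table: per-alternate comparisons, rates per 100,000 screens,
#' stage distribution, and the efficiency frontier; plus the implementation
#' surge when annual tallies are supplied.
#'
#' @param tallies Annual tallies, or `NULL` when `totals` are given directly.
#' @param totals Optional pre-summed totals (e.g. the packaged cumulative table).
#' @param referent Referent scenario name (default `"SQ"`).
#' @param window Reporting window applied to `tallies`.
#' @return List with `totals`, `comparisons` (named by alternate), `rates`,
#'   `stages`, `stage_shifts`, `frontier`, and `surge` (when computable).
#' @export
scenario_report <- function(tallies = NULL, totals = NULL, referent = "SQ",
                            window = c(2024L, 2043L)) {
  if (is.null(totals)) totals <- cumulate(tallies, window)
  totals <- as.data.table(totals)
  if (!referent %in% totals$scenario) stop("referent ", referent, " not present")
  alts <- setdiff(totals$scenario, referent)
  ref_row <- totals[scenario == referent]
  comparisons <- lapply(setNames(alts, alts), function(a)
    compare_scenarios(ref_row, totals[scenario == a]))
  stages <- if (any(grepl("^stage_", names(totals)))) stage_table(totals)
  list(
    totals = totals,
    comparisons = comparisons,
    rates = rates_table(totals),
    stages = stages,
    stage_shifts = if (!is.null(stages))
      lapply(setNames(alts, alts), function(a) stage_shift(stages, referent, a)),
    frontier = if (length(alts) >= 1) efficiency_frontier(comparisons),
    surge = if (!is.null(tallies) &&
                all(c(2023L, 2024L) %in% as.data.table(tallies)$year))
      implementation_surge(tallies, 2023L, 2024L)
  )
}

#' Serialize a scenario report to JSON
#'
#' @param report Output of [scenario_report()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_report_json() needs the jsonlite package")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, dataframe = "rows", digits = NA, null = "null")
  invisible(path)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the rounding used in the published tables (R's `round()` rounds
#' half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count the way the published narrative does
#'
#' Three significant digits with a K/M suffix above 10,000; smaller counts are
#' printed as integers.
#'
#' @param x Numeric counts.
#' @return Character, e.g. `"9.24 M"`, `"724 K"`, `"1804"`.
#' @export
fmt_count <- function(x) {
  one <- function(v) {
    av <- abs(v)
    if (av >= 1e6) paste(format(signif(v / 1e6, 3), trim = TRUE), "M")
    else if (av >= 1e4) paste(format(signif(v / 1e3, 3), trim = TRUE), "K")
    else format(round_half_up(v), trim = TRUE, scientific = FALSE)
  }
  vapply(x, one, character(1))
}
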