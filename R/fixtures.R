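#' Load a packaged published summary table
#'
#' The published tables are shipped verbatim as CSV fixtures with a numeric
#' checksum in the manifest guarding against accidental edits:
#' `"T2"` cumulative outcome totals per scenario 2024--2043, `"T3"` rates per
#' 100,000 screens, `"T4"` 2023-to-2024 changes, `"T5"` stage counts and
#' proportions, `"NARR"` the derived figures as printed in the results
#' narrative, `"TNM"` the stage lookup.
#'
#' @param table_id One of `"T2"`, `"T3"`, `"T4"`, `"T5"`, `"NARR"`, `"TNM"`.
#' @return `data.table` of the fixture.
#' @export
load_paper_table <- function(table_id) {
  wanted <- table_id
  man <- fread(system.file("extdata", "manifest.csv", package = "mammosim"))
  row <- man[man$table_id == wanted]
  if (nrow(row) != 1L)
    stop("unknown fixture table id: ", table_id)
  d <- fread(system.file("extdata", row$file, package = "mammosim"))
  num <- unlist(d[, vapply(d, is.numeric, TRUE), with = FALSE])
  if (abs(sum(num, na.rm = TRUE) - row$checksum) > 1e-6)
    stop("fixture ", table_id, " failed its checksum; the packaged table was edited")
  d
}

# printed decimal places of each rate column in the published per-100k table
TABLE3_DIGITS <- c(recalls_no_cancer = 0, biopsies = 0, negative_biopsies = 1,
                   invasive_dx = 0, screen_detected_dx = 0, bc_deaths = 1)

#' Recompute the per-100,000-screens table from the cumulative fixture
#'
#' Divides every outcome total in the packaged cumulative table by that
#' scenario's own screens total, scaled to 100,000 and rounded to the precision
#' of the printed rate table, and compares cell by cell.
#'
#' @param t2 Cumulative totals fixture (defaults to the packaged one).
#' @param t3 Printed rate fixture to compare against.
#' @return `data.table(scenario, outcome, computed_rate, printed_rate, matches)`
#'   with `computed_rate` rounded at printed precision.
#' @export
reproduce_table3 <- function(t2 = load_paper_table("T2"),
                             t3 = load_paper_table("T3")) {
  rates <- rates_table(t2)
  t3num <- copy(t3)
  num_cols <- setdiff(names(t3num), "scenario")
  t3num[, (num_cols) := lapply(.SD, as.numeric), .SDcols = num_cols]
  printed <- melt(t3num, id.vars = "scenario", variable.name = "outcome",
                  value.name = "printed_rate", variable.factor = FALSE)
  out <- merge(rates, printed, by = c("scenario", "outcome"), sort = FALSE)
  out[, computed_rate := round_half_up(rate, TABLE3_DIGITS[outcome])]
  out[, matches := computed_rate == printed_rate]
  out[, .(scenario, outcome, computed_rate, printed_rate, matches)]
}

#' Recompute every derived results-narrative figure from the packaged tables
#'
#' Re-derives, through the same comparison engine used for simulated tallies,
#' each absolute and relative figure quoted in the published results narrative:
#' additional screens / recalls without cancer / biopsies / negative biopsies /
#' invasive cancers / screen-detected cancers, deaths averted, and the
#' stage-specific differences -- all as alternate minus referent from the
#' cumulative and stage fixtures -- and compares them against the printed
#' figures at their printed precision.
#'
#' A value "matches" when it equals the printed figure at the precision the
#' narrative used (3 significant digits for K/M figures, exact integers
#' otherwise; percents at their printed decimals). `within_one` additionally
#' records agreement to within one unit, the slack the published narrative
#' itself needs against its own tables in a handful of places.
#'
#' @param t2,t5,narr Packaged fixtures (defaults load them).
#' @return `data.table(scenario, outcome, computed_value, computed_pct,
#'   printed_value, printed_pct, matches_value, matches_pct, within_one)`.
#' @export
reproduce_results_narrative <- function(t2 = load_paper_table("T2"),
                                        t5 = load_paper_table("T5"),
                                        narr = load_paper_table("NARR")) {
  ref <- t2[scenario == "SQ"]
  alts <- setdiff(t2$scenario, "SQ")

  rows <- list()
  for (a in alts) {
    cmp <- compare_scenarios(ref, t2[scenario == a])
    cc <- cmp[outcome != "bc_deaths",
              .(outcome, computed_value = absolute_difference,
                computed_pct = relative_change_pct)]
    rows[[a]] <- rbind(
      cc,
      data.table(outcome = "deaths_averted",
                 computed_value = attr(cmp, "deaths_averted"),
                 computed_pct = cmp[outcome == "bc_deaths", relative_change_pct])
    )[, scenario := a]
    sh <- stage_shift(t5, "SQ", a)
    rows[[paste0(a, "_stage")]] <- sh[, .(
      scenario = a, outcome = paste0("stage_", stage),
      computed_value = difference, computed_pct = relative_change_pct)]
  }
  comp <- rbindlist(rows, use.names = TRUE)
  out <- merge(narr, comp, by = c("scenario", "outcome"), sort = FALSE)

  # precision of a printed count: K/M figures carry 3 significant digits
  unit <- fifelse(abs(out$printed_value) >= 1e4,
                  10^(floor(log10(abs(out$printed_value))) - 2), 1)
  out[, matches_value := abs(computed_value - printed_value) <= unit / 2]
  out[, within_one := abs(computed_value - printed_value) <= pmax(unit / 2, 1)]
  dp <- vapply(out$printed_pct, function(v) {
    s <- format(v, trim = TRUE)
    if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
  }, integer(1))
  out[, matches_pct := is.na(printed_pct) |
        round_half_up(computed_pct, dp) == printed_pct]
  out[]
}

#' Verify internal consistency of the packaged cumulative and stage fixtures
#'
#' Checks that the stage proportions recomputed from the printed stage counts
#' match the printed proportions at two decimals, for every scenario.
#'
#' @param t5 Stage fixture.
#' @return `data.table` with computed and printed proportions and `matches`.
#' @export
reproduce_table5_proportions <- function(t5 = load_paper_table("T5")) {
  st <- stage_table(t5[, .(scenario, stage, count)])
  out <- merge(st, t5[, .(scenario, stage = factor(stage, STAGE_LEVELS), printed_pct = pct)],
               by = c("scenario", "stage"), sort = FALSE)
  out[, computed_pct := round_half_up(proportion_pct, 2)]
  # the printed table trims trailing zeros (e.g. 35.7); compare at its precision
  out[, matches := abs(computed_pct - printed_pct) < 0.005 + 1e-9]
  out[]
}
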