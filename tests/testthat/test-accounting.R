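t2 <- load_paper_table("T2")

# annual tallies whose 2024-2043 sums equal the packaged cumulative totals
fixture_tallies <- function() {
  cols <- c("screens", "recalls_no_cancer", "biopsies", "negative_biopsies",
            "invasive_dx", "screen_detected_dx", "bc_deaths")
  rbindlist(lapply(t2$scenario, function(sc) {
    out <- data.table(scenario = sc, year = 2024:2043)
    for (cc in cols) out[, (cc) := split_years(t2[scenario == sc][[cc]])]
    out
  }))
}

test_that("cumulate sums annual tallies exactly over the window", {
  tal <- fixture_tallies()
  tot <- cumulate(tal, c(2024, 2043))
  expect_equal(tot[scenario == "SQ", screens], 69573861)
  expect_equal(tot[scenario == "A40", bc_deaths], 124934)

  one <- cumulate(tal[scenario == "SQ"], c(2030, 2030))
  expect_equal(one$screens, tal[scenario == "SQ" & year == 2030, screens])

  zero <- copy(tal)[, (setdiff(names(tal), c("scenario", "year"))) := 0]
  expect_true(all(cumulate(zero, c(2024, 2043))[, !"scenario"] == 0))

  expect_error(cumulate(tal, c(2010, 2043)), "outside tally coverage")
})

test_that("comparisons implement the alternate-minus-referent formulas", {
  ref <- t2[scenario == "SQ"]
  cmp <- compare_scenarios(ref, t2[scenario == "A40"])
  expect_equal(cmp[outcome == "screens", absolute_difference], 9242624)
  expect_equal(round_half_up(cmp[outcome == "screens", relative_change_pct], 1), 13.3)
  expect_equal(attr(cmp, "deaths_averted"), 902)
  expect_equal(round_half_up(cmp[outcome == "bc_deaths", relative_change_pct], 2), -0.72)

  # identity and antisymmetry
  self <- compare_scenarios(ref, ref)
  expect_true(all(self$absolute_difference == 0))
  expect_true(all(self$relative_change_pct == 0))
  flip <- compare_scenarios(t2[scenario == "A40"], ref)
  expect_equal(flip$absolute_difference, -cmp$absolute_difference)

  # zero referent total: relative change undefined but flagged, difference kept
  z <- copy(ref); z$bc_deaths <- 0
  a <- copy(t2[scenario == "A40"]); a$bc_deaths <- 10
  cz <- compare_scenarios(z, a)
  expect_true(cz[outcome == "bc_deaths", undefined_relative])
  expect_true(is.na(cz[outcome == "bc_deaths", relative_change_pct]))
  expect_equal(cz[outcome == "bc_deaths", absolute_difference], 10)
})

test_that("per-100k rates divide by the scenario's own screens", {
  expect_equal(rate_per_100k(0, 123456), 0)
  expect_equal(round_half_up(rate_per_100k(124934, 78816485), 1), 158.5)
  expect_equal(round_half_up(rate_per_100k(300538, 69573861), 0), 432)
  expect_error(rate_per_100k(1, 0), "positive")
  # rate times screens recovers the total exactly before rounding
  r <- rate_per_100k(5461199, 69573861)
  expect_equal(r * 69573861 / 1e5, 5461199)
})

test_that("stage tables give proportions of all diagnoses", {
  one <- stage_table(data.table(scenario = "X", stage = "I", count = 1))
  expect_equal(one$proportion_pct, 100)

  t5 <- load_paper_table("T5")
  st <- stage_table(t5[, .(scenario, stage, count)])
  expect_equal(st[, sum(proportion_pct), by = scenario]$V1, rep(100, 5))
  expect_equal(round_half_up(st[scenario == "SQ" & stage == "I", proportion_pct], 2),
               38.94)

  sh <- stage_shift(t5, "SQ", "A40")
  expect_equal(sh[stage == "IV", difference], -415)
  expect_equal(round_half_up(sh[stage == "III", relative_change_pct], 1), -1.5)
})

test_that("implementation surge is plain year-over-year arithmetic", {
  tal <- data.table(scenario = "X", year = 2023:2024, screens = c(100, 125),
                    recalls_no_cancer = c(10, 10), biopsies = c(5, 0),
                    negative_biopsies = c(1, 1), invasive_dx = c(2, 2),
                    screen_detected_dx = c(1, 1), bc_deaths = c(0, 0))
  s <- implementation_surge(tal, 2023, 2024)
  expect_equal(s[outcome == "screens", change], 25)
  expect_equal(s[outcome == "screens", change_pct], 25)
  same <- implementation_surge(tal, 2023, 2023)
  expect_true(all(same$change == 0) && all(same$change_pct == 0, na.rm = TRUE))
  expect_true(is.na(s[outcome == "bc_deaths", change_pct]))  # flagged 0 baseline
  expect_error(implementation_surge(tal, 2022, 2024), "coverage")
})

test_that("the efficiency frontier sorts, slopes and flags ties", {
  ref <- t2[scenario == "SQ"]
  reports <- lapply(setdiff(t2$scenario, "SQ"),
                    function(a) compare_scenarios(ref, t2[scenario == a]))
  fr <- efficiency_frontier(reports)
  expect_identical(fr$alternate, c("B45", "A45", "B40", "A40"))
  # the segment between A45 and B40 is the steepest: the published inflection
  s_a45_b40 <- fr[alternate == "B40", slope]
  expect_equal(s_a45_b40, (582 - 539) / (4799329 - 4606252))
  expect_equal(s_a45_b40, max(fr$slope, na.rm = TRUE))

  single <- efficiency_frontier(reports[1])
  expect_true(is.na(single$slope))

  dup <- efficiency_frontier(list(reports[[1]], reports[[1]]))
  expect_true(any(dup$undefined_slope))
})

test_that("narrative-style count formatting matches the published style", {
  expect_identical(fmt_count(c(9242624, 4799329, 724365, 97402, 50010, 1804)),
                   c("9.24 M", "4.8 M", "724 K", "97.4 K", "50 K", "1804"))
})
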