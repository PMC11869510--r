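test_that("scenario definitions match the policy roster", {
  a40 <- build_scenario("A40", 0.50)
  expect_identical(a40$young_band, list(low = 40L, high = 49L, interval = 1L))
  expect_identical(a40$policy_start, 2024.0)

  b45 <- build_scenario("B45", 0.50)
  expect_identical(b45$young_band, list(low = 45L, high = 49L, interval = 2L))

  sq <- build_scenario("SQ", 0.50)
  expect_null(sq$young_band)
  expect_true(is.na(sq$target_participation))  # SQ ignores participation

  # core band identical across all five scenarios
  cores <- lapply(c("SQ", "A40", "B40", "A45", "B45"),
                  function(nm) build_scenario(nm)$core_band)
  expect_length(unique(cores), 1L)

  expect_error(build_scenario("X99"), "unknown scenario")
  expect_error(build_scenario("A40", 0), "target_participation")
})

test_that("participation model inverts the high/average risk mixture", {
  pm <- participation_model(0.50)
  expect_equal(pm$average_risk_enrollment, (0.50 - 0.25) / 0.75)
  expect_equal(participation_model(0.25)$average_risk_enrollment, 0)
  expect_equal(participation_model(1.00)$average_risk_enrollment, 1)
  # clamped at the low end
  expect_equal(participation_model(0.10)$average_risk_enrollment, 0)
})

test_that("offer schedules follow bands, intervals and the policy start", {
  # enrolled average-risk woman born 1990: annual 40-49 starting 2030, then core
  w <- make_women(1990)
  off <- offer_schedule(w, build_scenario("A40"))
  young <- off[program == "young"]
  expect_identical(young$age, 40:49)
  expect_true(all(young$date >= 2030 & young$date < 2041))
  # core offers run to 74 but the simulated window ends in 2051 (she is 61)
  expect_identical(off[program == "core", age], seq(50L, 60L, 2L))
  expect_true(all(diff(off$date) > 0))
  # a woman old enough to pass through the whole core band gets all 13 offers
  off_full <- offer_schedule(make_women(1965), build_scenario("SQ"))
  expect_identical(off_full[program == "core", age], seq(50L, 74L, 2L))

  # not enrolled: SQ and A40 schedules identical
  w2 <- make_women(1990, enrolled = FALSE)
  expect_identical(offer_schedule(w2, build_scenario("A40")),
                   offer_schedule(w2, build_scenario("SQ")))

  # born 1960: already >49 in 2024 -> core band only
  off3 <- offer_schedule(make_women(1960), build_scenario("A40"))
  expect_identical(unique(off3$program), "core")

  # woman mid-band at the policy start: biennial anchors at first eligibility
  w4 <- make_women(1980)  # turns 44 in 2024.5
  off4 <- offer_schedule(w4, build_scenario("B40"))[program == "young"]
  expect_identical(off4$age, c(44L, 46L, 48L))

  # high-risk women screen annually 40-49 in every scenario, before 2024 too
  w5 <- make_women(1978, risk_class = "high", enrolled = FALSE)
  off5 <- offer_schedule(w5, build_scenario("SQ"))[program == "young"]
  expect_identical(off5$age, 40:49)
  expect_true(any(off5$date < 2024))

  # no screen dates outside the simulated window
  w6 <- make_women(c(1941, 1955, 1975, 2005))
  for (nm in c("SQ", "A40", "B45")) {
    off6 <- offer_schedule(w6, build_scenario(nm))
    expect_true(all(off6$date >= 2015 & off6$date < 2052))
  }
})

test_that("schedules nest and counts are ordered across policies", {
  set.seed(11)
  w <- make_women(sample(1960:2005, 400, replace = TRUE))
  scen <- lapply(c(SQ = "SQ", A40 = "A40", B40 = "B40", A45 = "A45", B45 = "B45"),
                 build_scenario)
  off <- lapply(scen, function(s) offer_schedule(w, s))
  key <- function(o) paste(o$id, o$age)
  # subset relations that hold at the offer level
  expect_true(all(key(off$SQ) %in% key(off$A40)))
  expect_true(all(key(off$B40) %in% key(off$A40)))
  expect_true(all(key(off$B45) %in% key(off$A45)))
  expect_true(all(key(off$A45) %in% key(off$A40)))
  # band-entry anchoring makes B45 offers odd-aged, so only the count ordering
  # relates B45 to B40
  counts <- vapply(off, nrow, integer(1))
  expect_true(counts[["B45"]] <= counts[["B40"]])
  expect_true(counts[["B40"]] <= counts[["A40"]])
  expect_true(counts[["SQ"]] <= min(counts[c("B45", "A45", "B40", "A40")]))
})

test_that("offered screens are non-decreasing in target participation", {
  cfg1 <- sim_config(n_women = 8000, seed = 21, scenarios = "A40",
                     target_participation = 0.50)
  cfg2 <- sim_config(n_women = 8000, seed = 21, scenarios = "A40",
                     target_participation = 0.70)
  s1 <- run_simulation(cfg1)$tallies[, sum(screens)]
  s2 <- run_simulation(cfg2)$tallies[, sum(screens)]
  expect_lte(s1, s2)
})

test_that("attendance: first program offer certain, re-screens Bernoulli", {
  expect_true(all(attends(rep("high", 50), FALSE, runif(50))))
  expect_true(all(attends(rep("average", 50), TRUE, runif(50))))

  set.seed(42)
  n <- 10000
  att <- attends(rep("average", n), FALSE)
  se <- sqrt(0.63 * 0.37 / n)
  expect_lt(abs(mean(att) - 0.63), 3 * se)
})
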