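# minimal screen table + draw matrices for direct perform_screen tests
make_screens <- function(n, age = 60L, first = FALSE) {
  data.table(id = seq_len(n), program = "core", age = age,
             date = 1960 + age + 0.5, offer_index = 1L, attended = TRUE,
             risk_class = "average", is_first_screen = first)
}
make_draws <- function(n, seed) {
  set.seed(seed)
  m <- function() matrix(runif(n * 35), n, 35)
  list(u_screen = m(), u_biopsy_ref = m(), u_biopsy_pos = m())
}
no_history <- function() {
  h <- data.table(id = integer(), onset_age = numeric(), kind0 = character(),
                  growth_rate = numeric(), progression_age = numeric(),
                  node_age = numeric(), met_age = numeric(),
                  surfacing_age = numeric(), sojourn_years = numeric())
  setkey(h, id)
  h
}

test_that("sensitivity is monotone in size and gated at the threshold", {
  perf <- default_test_performance()
  sizes <- c(1, 2, 5, 10, 20, 50)
  s <- screen_sensitivity(sizes, 60, perf)
  expect_equal(s[1], 0)            # below detectability
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
  # the age penalty lowers sensitivity below 50
  expect_lt(screen_sensitivity(10, 45, perf), screen_sensitivity(10, 55, perf))
})

test_that("perfect specificity means no recalls without a tumor", {
  perf <- default_test_performance()
  perf$specificity_first <- 1; perf$specificity_subsequent <- 1
  ev <- perform_screen(make_screens(5000), no_history(), perf, make_draws(5000, 1))
  expect_identical(sum(ev$recall), 0L)
  expect_true(all(ev$result == "negative"))
})

test_that("perfect test and cascade always diagnoses a present tumor", {
  perf <- default_test_performance()
  perf$sens_intercept <- 50  # sensitivity 1 at any detectable size
  perf$biopsy_referral_prob_cancer <- 1; perf$biopsy_sensitivity <- 1
  h <- data.table(id = 1:100, onset_age = 50, kind0 = "invasive",
                  growth_rate = 0.35, progression_age = NA_real_,
                  node_age = Inf, met_age = Inf, surfacing_age = 90,
                  sojourn_years = 40)
  setkey(h, id)
  ev <- perform_screen(make_screens(100), h, perf, make_draws(100, 2))
  expect_true(all(ev$cancer_present))
  expect_true(all(ev$led_to_diagnosis))
})

test_that("false recall rate matches one minus specificity", {
  perf <- default_test_performance()
  n <- 100000
  ev <- perform_screen(make_screens(n, first = FALSE), no_history(), perf,
                       make_draws(n, 3))
  p <- 1 - perf$specificity_subsequent
  expect_lt(abs(mean(ev$recall) - p), 3 * sqrt(p * (1 - p) / n))
  # false recalls never yield positive biopsies
  expect_identical(sum(ev$biopsy_positive), 0L)
  # event-taxonomy invariants
  expect_true(all(!ev$biopsy | ev$recall))
  expect_true(all(!ev$led_to_diagnosis | (ev$biopsy & ev$biopsy_positive)))
})

test_that("diagnosis resolves to the earlier of screen and clinical surfacing", {
  pop <- make_women(1958, death_age = 80)        # born 1958.5
  h <- data.table(id = 1L, onset_age = 58, kind0 = "invasive", growth_rate = 0.3,
                  progression_age = NA_real_, node_age = 63.2, met_age = Inf,
                  surfacing_age = 62, sojourn_years = 4)
  setkey(h, id)

  # never screened: clinical diagnosis at surfacing, stage from state at 62
  res <- resolve_diagnosis(
    data.table(id = integer(), age = numeric(), date = numeric(),
               led_to_diagnosis = logical(), recall = logical(),
               biopsy = logical(), biopsy_positive = logical()),
    h, pop)
  expect_identical(res$diagnoses$detection_mode, "clinical")
  expect_equal(res$diagnoses$dx_age, 62)
  expect_identical(res$diagnoses$stage, classify_stage("invasive",
    tumor_size_at(h, 62), FALSE, FALSE))

  # screen-detected before surfacing: earlier stage, mode screen
  ev <- data.table(id = 1L, age = 60, date = 2018.5, led_to_diagnosis = TRUE,
                   recall = TRUE, biopsy = TRUE, biopsy_positive = TRUE)
  res2 <- resolve_diagnosis(ev, h, pop)
  expect_identical(res2$diagnoses$detection_mode, "screen")
  expect_equal(res2$diagnoses$dx_age, 60)
  lev <- c("0", "I", "II", "III", "IV")
  expect_lte(match(res2$diagnoses$stage, lev), match(res$diagnoses$stage, lev))

  # other-cause death before both: never becomes a case
  pop3 <- make_women(1958, death_age = 59)
  res3 <- resolve_diagnosis(ev[0], h, pop3)
  expect_identical(nrow(res3$diagnoses), 0L)
})

test_that("event counts satisfy the recall/biopsy identities in a full run", {
  cfg <- sim_config(n_women = 30000, seed = 404, scenarios = "A40",
                    keep_events = TRUE)
  ev <- run_simulation(cfg)$events$A40
  expect_identical(ev[, sum(recall)],
                   ev[, sum(recall & !led_to_diagnosis) + sum(led_to_diagnosis)])
  expect_lte(ev[, sum(biopsy & !biopsy_positive)], ev[, sum(biopsy)])
  expect_lte(ev[, sum(biopsy)], ev[, sum(recall)])
  # ... and the annual tally mirrors the event log
  tal <- build_tally("A40", ev, data.table(id = integer(), dx_date = numeric(),
    dx_age = numeric(), death_age = numeric(), cause = character(),
    stage = character(), detection_mode = character()),
    make_women(2000), c(2015, 2051))
  expect_equal(sum(tal$screens), nrow(ev))
})

test_that("recall-without-cancer rate per screen is policy-insensitive", {
  cfg <- sim_config(n_women = 60000, seed = 505)
  tot <- cumulate(run_simulation(cfg)$tallies, c(2024, 2043))
  rate <- tot[, recalls_no_cancer / screens]
  expect_lt(diff(range(rate)) / mean(rate), 0.03)
})
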