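#' Default other-cause life table
#'
#' A Gompertz-style annual mortality schedule for ages 0--119 standing in for
#' a national female life table: hazard `h(a) = bg + alpha * exp(beta * a)`,
#' converted to annual death probabilities `q(a) = 1 - exp(-h(a))`, with
#' `q(119) = 1` so that no one outlives age 119.
#'
#' @param alpha,beta Gompertz level and slope (per year of age).
#' @param background Age-constant background hazard.
#' @return `data.frame` with columns `age` (0--119) and `qx` in `[0, 1]`.
#' @export
default_life_table <- function(alpha = 2e-5, beta = 0.097, background = 4e-4) {
  age <- 0:119
  qx <- 1 - exp(-(background + alpha * exp(beta * age)))
  qx[age == 119] <- 1
  data.frame(age = age, qx = qx)
}

#' Default age-specific tumor onset hazard
#'
#' Piecewise-constant annual onset hazard for an average-risk woman, by single
#' year of age. The default steps up from zero before age 25 to a plateau in
#' old age, shaped like published female breast cancer incidence shifted
#' earlier by roughly the mean preclinical sojourn, and scaled so that the
#' population-average cumulative onset by age 80 (averaging high- and
#' average-risk women) is about 12%.
#'
#' @return `data.frame(age = 0:119, rate)` of annual onset hazards.
#' @export
default_onset_hazard <- function() {
  band_start <- c(0, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 100)
  pop_rate <- c(0, 5e-5, 1.5e-4, 5e-4, 1.6e-3, 2.1e-3, 2.4e-3, 2.9e-3,
                3.5e-3, 3.9e-3, 4.1e-3, 4.2e-3, 3.8e-3, 3.0e-3, 2.0e-3, 1.0e-3)
  age <- 0:119
  # average-risk level: population mix is 0.25*hr + 0.75 at hr_high = 2.5
  data.frame(age = age, rate = pop_rate[findInterval(age, band_start)] / 1.375)
}

#' Default natural-history parameters
#'
#' Tumor onset follows the age-specific hazard table `onset_hazard`
#' (see [default_onset_hazard()]), multiplied by `hr_high` for high-risk women. Tumor
#' diameter grows exponentially from `d0_mm` with a lognormal per-woman rate.
#' Nodal and metastatic spread are size-triggered: each tumor draws lognormal
#' diameter thresholds at which it becomes node-positive and metastatic
#' (metastasis never before node positivity), so the probability of spread at a
#' given size does not depend on how fast the tumor grew -- the property that
#' makes the stage mix stable under detection-time shifts. Symptomatic
#' surfacing hazard is proportional to diameter. A fixed fraction of onsets
#' start as DCIS, of which `dcis_progression_prob` progress to invasive
#' disease after an exponential dwell; spread only occurs once a history is
#' invasive.
#'
#' Defaults were desk-calibrated once so that, under the status-quo policy,
#' cumulative onset by age 80 sits near 10--13% and the simulated stage mix and
#' per-screen rates are of the order published for Canadian screening; they are
#' not a calibration to any specific registry.
#'
#' @return Named list of natural-history parameters.
#' @export
default_nh_params <- function() {
  list(
    onset_hazard    = default_onset_hazard(),
    hr_high         = 2.5,     # onset hazard ratio, high-risk vs average
    dcis_fraction   = 0.12,    # share of onsets starting as DCIS
    dcis_progression_prob = 0.5,
    dcis_dwell_mean = 4,       # years; exponential DCIS->invasive dwell
    d0_mm           = 2,       # diameter at onset (screen-detectable origin)
    growth_meanlog  = log(0.35), # lognormal log-diameter growth rate (per year)
    growth_sdlog    = 0.5,
    size_cap_mm     = 128,     # growth saturates here
    node_size_meanlog = log(18), # lognormal node-positivity size threshold (mm)
    node_size_sdlog   = 0.9,
    met_size_meanlog  = log(90), # lognormal metastasis size threshold (mm)
    met_size_sdlog    = 0.9,
    surfacing_hazard_per_mm = 0.013 # clinical surfacing hazard per mm diameter
  )
}

#' Default screening test performance
#'
#' Mammography sensitivity is logistic in log tumor diameter with a penalty
#' below age 50 (denser tissue), and zero below `detect_min_mm`. Specificity is
#' lower at a woman's first-ever screen than at subsequent screens. Recalls
#' with a tumor present always proceed to biopsy; recalls without cancer
#' proceed with probability `biopsy_referral_prob`.
#'
#' @return Named list of test-performance parameters.
#' @export
default_test_performance <- function() {
  list(
    detect_min_mm         = 2,
    sens_intercept        = -1.4,  # logit at size_ref_mm, age >= 50
    sens_log_size_slope   = 2.6,
    size_ref_mm           = 5,
    sens_age_young_shift  = -0.4,  # logit shift below age 50
    sens_scale            = 1,     # multiplies sensitivity; 0 disables detection
    specificity_first     = 0.93,
    specificity_subsequent = 0.95,
    biopsy_referral_prob  = 0.12,  # given recall without cancer
    biopsy_referral_prob_cancer = 1.0, # given recall with tumor present
    biopsy_sensitivity    = 0.95
  )
}

#' Default stage-specific survival model
#'
#' Time from clinical surfacing to breast-cancer death is Weibull with a
#' stage-specific median among women who die of the disease, and a
#' stage-specific cured fraction who die of other causes. Both are ordered in
#' stage so that survival at an earlier stage first-order dominates survival at
#' any later stage. Values are in the range of long-term stage-specific net
#' survival reported for high-income countries; they are documented defaults,
#' not a registry calibration.
#'
#' @return Named list with `shape`, and per-stage `median_years` / `cure_fraction`
#'   (names `"0"`, `"I"`, `"II"`, `"III"`, `"IV"`).
#' @export
default_survival_model <- function() {
  list(
    shape = 1.1,
    median_years  = c("0" = 12, "I" = 10, "II" = 8, "III" = 5, "IV" = 2.5),
    cure_fraction = c("0" = 0.98, "I" = 0.94, "II" = 0.82, "III" = 0.55, "IV" = 0.15)
  )
}

#' Assemble and validate a simulation run configuration
#'
#' @param n_women Number of simulated women (>= 1).
#' @param seed Integer seed; mandatory, drives every random draw of the run.
#' @param scenarios Character vector of scenario names among
#'   `c("SQ","A40","B40","A45","B45")`; the referent `SQ` is always sensible to include.
#' @param target_participation Target overall participation of women in the
#'   revised young-age programs (0.50 default; the published scenarios use
#'   0.50/0.70/1.00).
#' @param start_year,end_year Reporting window of calendar years simulated.
#' @param growth_rate Annual birth-cohort growth rate (>= 0).
#' @param represented_women Real-population size the simulated sample stands
#'   for; per-woman weight is `represented_women / n_women`.
#' @param life_table `data.frame(age, qx)` covering ages 0--119 with
#'   probabilities in `[0,1]` and `qx[age==119] == 1`.
#' @param nh,perf,surv Parameter blocks; see [default_nh_params()],
#'   [default_test_performance()], [default_survival_model()].
#' @param keep_events Keep the per-screen event log in the run result
#'   (needed for event-level audits and window-unique women-screened counts).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_women = 200000L,
                       seed,
                       scenarios = c("SQ", "A40", "B40", "A45", "B45"),
                       target_participation = 0.50,
                       start_year = 2015L, end_year = 2051L,
                       growth_rate = 0.01,
                       represented_women = 15e6,
                       life_table = default_life_table(),
                       nh = default_nh_params(),
                       perf = default_test_performance(),
                       surv = default_survival_model(),
                       keep_events = FALSE) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("config error at `seed`: a single integer seed is mandatory")
  check_scenario_names(scenarios)
  if (!is.numeric(n_women) || length(n_women) != 1L || n_women < 1)
    stop("config error at `n_women`: need at least 1 simulated woman")
  if (target_participation <= 0 || target_participation > 1)
    stop("config error at `target_participation`: must be in (0, 1]")
  if (growth_rate < 0) stop("config error at `growth_rate`: must be >= 0")
  validate_life_table(life_table)
  validate_nh_params(nh)
  validate_test_performance(perf)
  validate_survival_model(surv)
  structure(list(
    n_women = as.integer(n_women), seed = as.integer(seed),
    scenarios = scenarios, target_participation = target_participation,
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    growth_rate = growth_rate, represented_women = represented_women,
    life_table = life_table, nh = nh, perf = perf, surv = surv,
    keep_events = isTRUE(keep_events)
  ), class = "sim_config")
}

check_scenario_names <- function(names) {
  bad <- setdiff(names, c("SQ", "A40", "B40", "A45", "B45"))
  if (length(bad))
    stop("config error at `scenarios`: unknown scenario name(s) ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

validate_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt)))
    stop("config error at `life_table`: need columns `age` and `qx`")
  if (!identical(as.integer(lt$age), 0:119))
    stop("config error at `life_table`: must cover ages 0..119 exactly")
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0 | lt$qx > 1))
    stop("config error at `life_table.qx`: probabilities must lie in [0, 1]")
  if (lt$qx[lt$age == 119] != 1)
    stop("config error at `life_table.qx`: terminal probability at age 119 must be 1")
  invisible(TRUE)
}

validate_nh_params <- function(p) {
  oh <- p$onset_hazard
  if (!is.data.frame(oh) || !all(c("age", "rate") %in% names(oh)))
    stop("config error at `nh.onset_hazard`: need columns `age` and `rate`")
  if (!identical(as.integer(oh$age), 0:119))
    stop("config error at `nh.onset_hazard`: must cover ages 0..119 exactly")
  if (any(!is.finite(oh$rate)) || any(oh$rate < 0))
    stop("config error at `nh.onset_hazard.rate`: hazards must be finite and >= 0")
  pos <- c("hr_high", "d0_mm", "size_cap_mm", "dcis_dwell_mean",
           "node_size_sdlog", "met_size_sdlog")
  nonneg <- c("surfacing_hazard_per_mm")
  for (f in c(pos, nonneg)) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]))
      stop("config error at `nh.", f, "`: missing or non-finite")
    if (p[[f]] < 0) stop("config error at `nh.", f, "`: hazard/scale must be >= 0")
  }
  for (f in pos) if (p[[f]] <= 0) stop("config error at `nh.", f, "`: must be > 0")
  for (f in c("dcis_fraction", "dcis_progression_prob"))
    if (p[[f]] < 0 || p[[f]] > 1) stop("config error at `nh.", f, "`: must be in [0, 1]")
  invisible(TRUE)
}

validate_test_performance <- function(p) {
  probs <- c("specificity_first", "specificity_subsequent", "biopsy_referral_prob",
             "biopsy_referral_prob_cancer", "biopsy_sensitivity", "sens_scale")
  for (f in probs)
    if (is.null(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stop("config error at `perf.", f, "`: must be a probability in [0, 1]")
  if (p$specificity_first > p$specificity_subsequent)
    stop("config error at `perf.specificity_first`: first-screen specificity ",
         "cannot exceed subsequent-screen specificity")
  invisible(TRUE)
}

validate_survival_model <- function(s) {
  st <- c("0", "I", "II", "III", "IV")
  if (!all(st %in% names(s$median_years)) || !all(st %in% names(s$cure_fraction)))
    stop("config error at `surv`: median_years and cure_fraction must name stages ",
         paste(st, collapse = ", "))
  if (any(s$median_years[st] <= 0)) stop("config error at `surv.median_years`: must be > 0")
  if (any(s$cure_fraction[st] < 0 | s$cure_fraction[st] > 1))
    stop("config error at `surv.cure_fraction`: must be in [0, 1]")
  # stage ordering: worse stage => shorter survival, smaller cured fraction
  if (is.unsorted(rev(s$median_years[st])))
    stop("config error at `surv.median_years`: must be non-increasing in stage")
  if (is.unsorted(rev(s$cure_fraction[st])))
    stop("config error at `surv.cure_fraction`: must be non-increasing in stage")
  invisible(TRUE)
}
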