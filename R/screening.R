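#' Mammography sensitivity
#'
#' Logistic in log diameter with an age penalty below 50, zero below the
#' detectability threshold, scaled by `sens_scale` (0 disables detection).
#'
#' @param size_mm Tumor diameter in mm.
#' @param age Age at screen in years.
#' @param perf Test-performance parameters, see [default_test_performance()].
#' @return Detection probabilities in `[0, 1]`, non-decreasing in size.
#' @export
screen_sensitivity <- function(size_mm, age, perf = default_test_performance()) {
  logit <- perf$sens_intercept +
    perf$sens_log_size_slope * log(size_mm / perf$size_ref_mm) +
    perf$sens_age_young_shift * (age < 50)
  perf$sens_scale * plogis(logit) * (size_mm >= perf$detect_min_mm)
}

#' Perform screens on attended offers
#'
#' Resolves each attended screen against the woman's latent disease state at
#' the screen age: with a detectable tumor present the screen recalls with
#' probability `sensitivity(size, age)`; without one it recalls with
#' probability `1 - specificity` (first versus subsequent screen). Recalls with
#' a tumor proceed to biopsy with probability `biopsy_referral_prob_cancer` and
#' the biopsy is positive with probability `biopsy_sensitivity`; recalls
#' without cancer proceed to biopsy with probability `biopsy_referral_prob` and
#' are always negative (absent disease is never overcalled). A screen leads to
#' diagnosis exactly when its biopsy is positive.
#'
#' Uniform draws are keyed by (woman, age) so that scenarios sharing an offer
#' age share its outcome (common random numbers).
#'
#' @param screens Attended rows of [mark_attendance()] output (columns id, age,
#'   date, is_first_screen).
#' @param histories [sample_tumor_history()] table.
#' @param perf Test-performance parameters.
#' @param draws List of matrices `u_screen`, `u_biopsy_ref`, `u_biopsy_pos`
#'   (`[n_women, ages 40..74]`, rows indexed by id).
#' @param nh Natural-history parameters (sizing).
#' @return `screens` with columns cancer_present, size_mm, result
#'   (`"negative"`/`"recall"`), recall, biopsy, biopsy_positive,
#'   led_to_diagnosis.
#' @export
perform_screen <- function(screens, histories, perf, draws, nh = default_nh_params()) {
  sc <- copy(screens)
  sc[histories, `:=`(onset_age = i.onset_age, growth_rate = i.growth_rate,
                     surfacing_age = i.surfacing_age), on = "id"]
  sc[, cancer_present := !is.na(onset_age) & onset_age <= age & age < surfacing_age]
  sc[, size_mm := fifelse(cancer_present,
                          pmin(nh$size_cap_mm, nh$d0_mm * exp(growth_rate * (age - onset_age))),
                          NA_real_)]
  col <- sc$age - 39L
  u_screen <- draws$u_screen[cbind(sc$id, col)]
  u_ref <- draws$u_biopsy_ref[cbind(sc$id, col)]
  u_pos <- draws$u_biopsy_pos[cbind(sc$id, col)]

  sens <- screen_sensitivity(sc$size_mm, sc$age, perf)
  fpr <- 1 - fifelse(sc$is_first_screen, perf$specificity_first,
                     perf$specificity_subsequent)
  sc[, recall := fifelse(cancer_present, u_screen < sens, u_screen < fpr)]
  sc[, biopsy := recall & fifelse(cancer_present,
                                  u_ref < perf$biopsy_referral_prob_cancer,
                                  u_ref < perf$biopsy_referral_prob)]
  sc[, biopsy_positive := biopsy & cancer_present & u_pos < perf$biopsy_sensitivity]
  sc[, led_to_diagnosis := biopsy_positive]
  sc[, result := fifelse(recall, "recall", "negative")]
  sc[, c("onset_age", "growth_rate", "surfacing_age") := NULL]
  sc[]
}

#' Resolve each woman's diagnosis from screens and latent history
#'
#' Diagnosis occurs at the earlier of the first screen that led to diagnosis
#' and the clinical surfacing age, truncated by other-cause death and the
#' age-119 cap; stage is the history's state (kind, size, N, M) at the
#' diagnosis age. Screen events after the diagnosis (or death) never happen and
#' are dropped.
#'
#' @param screen_events Output of [perform_screen()].
#' @param histories [sample_tumor_history()] table.
#' @param pop Population table (for death ages and birth dates).
#' @param nh Natural-history parameters.
#' @return List with `diagnoses` (id, dx_age, dx_date, detection_mode, stage,
#'   kind, size_mm, node_positive, metastasis, surfacing_age) and `events`
#'   (the screen events that actually occur).
#' @export
resolve_diagnosis <- function(screen_events, histories, pop, nh = default_nh_params()) {
  ev <- copy(screen_events)
  led <- ev[led_to_diagnosis == TRUE]
  first_dx <- if (nrow(led)) led[, .(screen_dx_age = min(age)), by = id]
              else data.table(id = integer(), screen_dx_age = numeric())

  dx <- histories[, .(id, surfacing_age)]
  dx[pop, `:=`(other_cause_death_age = i.other_cause_death_age,
               birth_date = i.birth_date), on = "id"]
  dx[first_dx, screen_dx_age := i.screen_dx_age, on = "id"]
  dx[, dx_age := pmin(surfacing_age, screen_dx_age, na.rm = TRUE)]
  dx[, detection_mode := fifelse(!is.na(screen_dx_age) & screen_dx_age < surfacing_age,
                                 "screen", "clinical")]
  # the woman only becomes a case if diagnosis precedes death and the age cap
  dx <- dx[dx_age < pmin(other_cause_death_age, 119)]

  st <- tumor_state_at(histories[.(dx$id)], dx$dx_age, nh)
  dx[, `:=`(kind = st$kind, size_mm = st$size_mm,
            node_positive = st$node_positive, metastasis = st$metastasis)]
  dx[, stage := classify_stage(kind, size_mm, node_positive, metastasis)]
  dx[, dx_date := birth_date + dx_age]
  dx[, c("other_cause_death_age", "birth_date") := NULL]

  # drop screens that can no longer happen (post-diagnosis; death already
  # filtered at scheduling); keep the diagnosing screen itself
  ev[dx, dx_age := i.dx_age, on = "id"]
  ev <- ev[is.na(dx_age) | age < dx_age | (age == dx_age & led_to_diagnosis)]
  ev[, dx_age := NULL]
  list(diagnoses = dx[], events = ev[])
}
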