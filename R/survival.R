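#' Quantile of the stage-specific time to breast-cancer death
#'
#' The stage-`s` distribution is a cure-mixture Weibull: with probability
#' `cure_fraction[s]` the woman never dies of breast cancer; otherwise the time
#' from clinical surfacing to breast-cancer death is Weibull with the
#' configured stage median. Inverting the mixture CDF at a shared quantile `u`
#' gives `Inf` (cured) when `u > 1 - cure_fraction[s]`. Because both the cured
#' fraction and the median are non-increasing in stage, the mixture CDFs are
#' pointwise ordered, so for any fixed `u` the death time never decreases when
#' the stage improves -- the property the lead-time guard relies on.
#'
#' @param u Quantiles in (0, 1), one per woman, shared across scenarios.
#' @param stage Stage at detection (`"0"`, `"I"`, ..., `"IV"`), vectorized.
#' @param surv Survival model, see [default_survival_model()].
#' @return Years from clinical surfacing to breast-cancer death (`Inf` = cured).
#' @export
bc_survival_quantile <- function(u, stage, surv = default_survival_model()) {
  cure <- surv$cure_fraction[stage]
  scale <- surv$median_years[stage] / log(2)^(1 / surv$shape)
  t <- qweibull(pmin(u / (1 - cure), 1), shape = surv$shape, scale = scale)
  fifelse(u <= 1 - cure, t, Inf)
}

#' Assign breast-cancer death ages to diagnosed women
#'
#' Lead-time guard: one uniform quantile per woman (common across scenarios) is
#' pushed through the survival distribution of the stage AT DETECTION, but the
#' resulting survival time is anchored at the CLINICAL SURFACING age, which is a
#' property of the latent history and identical in every scenario. Earlier
#' (screen) detection therefore only changes the outcome through the stage --
#' an equal-or-later breast-cancer death, never credit for lead time alone.
#' Death ages are capped downstream at 119 by [adjudicate_death()].
#'
#' @param diagnoses Diagnosis table from [resolve_diagnosis()] (columns id,
#'   stage, surfacing_age).
#' @param u Uniform quantile per diagnosed woman (aligned with `diagnoses`).
#' @param surv Survival model.
#' @return Numeric breast-cancer death ages (`Inf` where cured).
#' @export
sample_bc_death_age <- function(diagnoses, u, surv = default_survival_model()) {
  if (nrow(diagnoses) == 0) return(numeric(0))
  stopifnot(length(u) == nrow(diagnoses))
  diagnoses$surfacing_age + bc_survival_quantile(u, diagnoses$stage, surv)
}

#' Adjudicate cause and age of death
#'
#' Death age is the minimum of the breast-cancer death age (if any), the
#' other-cause death age, and the age cap 119; the cause is whichever bound
#' binds, with ties broken as other-cause.
#'
#' @param bc_death_age Breast-cancer death ages (`Inf`/`NA` = none).
#' @param other_cause_death_age Other-cause death ages (<= 119).
#' @return `data.table(death_age, cause)` with cause in
#'   `c("breast_cancer", "other")`.
#' @export
#' @examples
#' adjudicate_death(c(70, NA), c(65, 88))
adjudicate_death <- function(bc_death_age, other_cause_death_age) {
  bc <- fifelse(is.na(bc_death_age), Inf, bc_death_age)
  other <- pmin(other_cause_death_age, 119)
  data.table(
    death_age = pmin(bc, other, 119),
    cause = fifelse(bc < other & bc < 119, "breast_cancer", "other")
  )
}
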