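---
title: "Modelling breast cancer screening scenarios with mammosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling breast cancer screening scenarios with mammosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosim)
library(data.table)
```

## What the package models

mammosim compares five organized mammography policies for a Canadian-style
female population over calendar years 2015–2051. The referent, status quo
(`SQ`), offers biennial screening at ages 50–74 with roughly 25% of women aged
40–49 — the high-risk quarter of the population — already screening annually.
Four revisions start on 2024-01-01 and additionally enrol average-risk women in
a young-age band: annual or biennial screening at ages 40–49 (`A40`, `B40`) or
45–49 (`A45`, `B45`), at a target overall participation of 50% by default.

The package has two layers that deliberately share one code path:

* an **accounting layer** that turns per-scenario outcome totals into the
  published derived statistics — absolute and relative differences versus the
  referent, rates per 100,000 screens, stage distributions and shifts,
  implementation-year surges, and the deaths-averted efficiency frontier.
  Applied to the packaged published cumulative tables it reproduces the
  published downstream figures exactly (see `reproduce_table3()`,
  `reproduce_table5_proportions()`, `reproduce_results_narrative()`);
* a **microsimulation layer** that generates those totals from individual
  histories, so the same reports can be computed for counterfactual settings.

Absolute simulated counts are *not* expected to match the published cumulative
totals: the original platform's calibrated natural-history inputs are not
public. The simulator is a parameterized, documented stand-in whose defaults
were chosen once for realism; what carries over are structural properties
(orderings under coupled randomness, count identities, the first-year surge
pattern, the direction of the stage shift), and those are what the test suite
asserts about it.

## Natural history

Each woman may develop at most one first primary tumor.

* **Onset.** An age-specific piecewise-constant hazard (`default_onset_hazard()`,
  per-year rates by single year of age) is inverted by sampling one exponential
  quantile per woman. High-risk women (25% of the population) carry a hazard
  ratio of 2.5. The default table is shaped like female breast cancer incidence
  shifted a few years earlier (onset precedes diagnosis by the sojourn time)
  and scaled so that population-average cumulative onset by age 80 is ≈11.5%,
  within the 10–13% band the tests assert.
* **Growth.** Diameter grows exponentially from 2 mm (the detectable origin)
  with a per-tumor lognormal rate, `log`-mean `log(0.35)`/year and `log`-SD 0.5
  (diameter doubling time ≈ 2 years at the median), capped at 128 mm.
* **DCIS.** 12% of onsets start as ductal carcinoma in situ; half of those
  progress to invasive disease after an exponential dwell with mean 4 years.
  DCIS can be screen-detected (stage 0) or, less often, surface clinically;
  nodal and distant spread require invasive disease.
* **Spread.** Each tumor draws a lognormal *size threshold* for node positivity
  (median 18 mm, `log`-SD 0.9) and for metastasis (median 90 mm, `log`-SD 0.9,
  floored at the nodal threshold so spread is ordered). A transition happens
  when the growth curve crosses the threshold. Size thresholds — rather than
  hazards in calendar time — make P(spread | size) independent of growth rate.
  This matters: with time-based spread hazards, slowly growing tumors are both
  more advanced at any given size *and* more likely to be censored by death,
  and the diagnosed stage mix collapses toward stage I. The threshold form
  keeps the stage-given-size distribution stable under shifts in detection
  time, which is precisely the property a stage-shift analysis rests on.
* **Clinical surfacing.** Symptomatic detection has hazard 0.013 per mm of
  diameter per year, giving a closed-form inverse, a median onset-to-surfacing
  sojourn of ≈6 years and a median diameter at clinical diagnosis of ≈20 mm.
  Every history surfaces in finite time; death may pre-empt it.
* **Staging.** A simplified TNM lookup shipped as a versioned CSV
  (`tnm_stage_map()`): T1 < 20 mm ≤ T2 ≤ 50 mm < T3, N0/N1, M0/M1, grouped as
  stage I = T1N0; II = T1N1, T2 (either N), T3N0; III = T3N1; IV = any M1;
  DCIS = stage 0. The grouping collapses the standard anatomic stage groups
  under a binary nodal status. The function is total and monotone: growing or
  spreading never lowers the stage.

## Screening process

Offers fall on birthday anniversaries. High-risk women are offered annual
screens at 40–49 in every scenario and year; enrolled average-risk women are
offered the scenario's young band from their first band-eligible birthday on or
after 2024-01-01 (biennial phases anchor at that first offer); everyone is
offered the core band, even ages 50–74. Enrolment is a single per-woman
Bernoulli draw — target participation `t` translates to an average-risk
enrolment probability `(t − 0.25)/0.75`, so `t = 0.25` reduces every revision
to the status quo exactly.

The first offer of each program (young band; core band) is attended with
probability 1; later offers independently with the re-screen rate, 1.00 for
high-risk and 0.63 for average-risk women. Reading the first-offer guarantee
*per program* (rather than once per lifetime) keeps a woman's status-quo
schedule a subset of her revised-scenario schedule under shared draws, which is
what makes the policy comparisons clean per woman.

Test performance: sensitivity is logistic in log diameter
(`plogis(-1.4 + 2.6·log(d/5 mm))`, ≈0.2 at 5 mm, ≈0.8 at 15 mm), shifted down
by 0.4 logits below age 50 (denser tissue) and zero below 2 mm; specificity is
0.93 at a woman's first-ever screen and 0.95 at subsequent screens. Recalls
with a tumor present always proceed to biopsy and the biopsy is positive with
probability 0.95; recalls without cancer are biopsied with probability 0.12 and
are always negative — absent disease is never overcalled, so "recall without
cancer" and "negative biopsy" mean exactly what the outcome definitions say. A
single shared referral probability would have throttled true detection by the
same 0.12 and made screen detection negligible, so the two referral paths are
separate parameters. With these defaults the recall-without-cancer rate is
≈5,200 per 100,000 screens — below the published ≈7,850, a known consequence of
pairing a 0.93/0.95 specificity with this cascade; the scenario *differences*,
which are what the analysis reports, are insensitive to that level.

Diagnosis resolves at the earlier of the first screen whose biopsy is positive
and clinical surfacing, truncated by other-cause death and the age cap of 119;
stage is the history's state at that age. Interval cancers are simply clinical
surfacing between screens.

## Survival and the lead-time guard

Time from *clinical surfacing* to breast-cancer death is a cure-mixture
Weibull by stage at detection: shape 1.1, medians 12/10/8/5/2.5 years among
women who die of the disease, cured fractions 0.98/0.94/0.82/0.55/0.15 for
stages 0/I/II/III/IV. Both sequences are monotone in stage, so the mixture
CDFs are pointwise ordered.

Lead-time bias is excluded by construction. Each woman draws one survival
quantile, shared across scenarios, and her death age is
`clinical surfacing age + quantile(stage at detection)`. The anchor is a
property of the latent history, identical in every scenario; detection mode
changes the outcome only through the stage. Earlier detection therefore yields
an equal-or-later death age for the same quantile — screening is never
credited for merely starting the clock earlier. Death is adjudicated against
other-cause mortality (a Gompertz-style life table, certain death by 119) by
taking the earlier cause, ties to other causes.

## Common random numbers

One seeded stream draws the population, all latent histories, the per-woman
enrolment and survival quantiles, and uniforms keyed by (woman, age) for
attendance, screen outcome, biopsy referral and biopsy result — all before the
scenario loop. Two consequences are tested: a scenario's results do not depend
on which other scenarios run alongside it, and facing the same offer at the
same age gives the same outcome in every scenario, so between-scenario
differences are purely policy-induced.

At desk scale the coupling has limits worth stating. With 1–2 × 10⁵ simulated
women the deaths-averted totals are a few raw counts per scenario — the same
*relative* magnitude as the published analysis (≈0.7% of deaths for the most
intensive revision) — so orderings between the closest pairs (biennial 40–49
versus biennial 45–49 in particular) hold in expectation but can tie or flip
in a single run. The biennial 40–49 band anchored at age 40 screens only even
ages, leaving its 45–49 coverage below the 45–49 annual-equivalent; its
mortality margin over biennial 45–49 is ≈30% more averted deaths, matching the
published ratio, but that is 1–3 raw deaths at these problem sizes.

## Numerical and design choices

* Dates are fractional years; a screen's calendar year is the year containing
  its date, and screens exist only in 2015–2051. Other-cause death ages are
  integer years (the life table's natural resolution); breast-cancer death ages
  are continuous, so cause ties have measure zero and resolve to other causes.
* Biennial young-band schedules anchor at the first eligible offer (band entry
  or 2024, whichever is later), answering an ambiguity the policy description
  leaves open; the core band anchors at age 50 for everyone.
* The 63% re-screen rate is applied per offer, independently — the simplest
  reading of a re-screen rate; persistent adherence classes are a plausible
  alternative not modelled.
* Degenerate inputs are first-class: a zero onset hazard yields no disease, a
  zero sensitivity scale yields purely clinical diagnosis, perfect specificity
  yields zero false recalls, and participation at the 25% baseline reproduces
  the status quo byte-for-byte. These are the oracles the test suite uses.
* Tallies are weighted counts (weight = represented population / simulated
  women, constant within a run, 75 at the default 200,000 women representing
  15 million); written CSVs are byte-reproducible given the seed.
* The packaged published tables are loaded through a checksum guard;
  every "golden" expectation in the tests traces to a fixture cell or to
  arithmetic on fixture cells. Where the published narrative disagrees with
  its own tables (seven absolute figures one unit below the table arithmetic,
  one rate cell and one percent one unit off), the tests assert the table
  arithmetic exactly and the narrative figure to within one unit.

## Problem sizes

Module tests run at 10⁴–10⁵ women or histories; the property-based acceptance
of the simulator uses a coupled five-scenario run of 100,000 women (seed fixed)
plus degenerate-parameter runs of 50,000; the analysis scripts default to
200,000 women. A coupled five-scenario run of 200,000 women takes ≈30 s and
≈2 GB on one core.

## What the generator does and does not emulate

It emulates: birth-cohort growth (1%/year), a 25%/75% high/average risk split,
age-specific onset, DCIS and invasive disease with growth and ordered spread,
screen versus clinical detection with first-screen specificity penalties, the
recall→biopsy cascade, stage-dependent survival with competing mortality, and
policy schedules with imperfect participation and re-screening.

It does not emulate: provincial calibration or migration, breast density,
molecular subtypes, second primaries, multi-step diagnostic imaging,
radiologist variability, treatment effects beyond the stage-specific survival
distributions, or costs. Passing tests therefore support the *accounting
layer's* exactness and the simulator's *structural* behaviour — not the claim
that its absolute counts describe any real population.

## Known limitations

* Binary nodal status compresses stage III (≈3–4% of diagnoses versus ≈12%
  published); with only N0/N1 available, most node-positive disease lands in
  stage II. Stage-shift *differences* between scenarios still behave correctly.
* The pre-2015 screening history is not simulated, so the first simulated
  years over-count first screens among women already 50+; the 2024–2043
  reporting window sits well past this burn-in.
* Deaths-averted comparisons between near-identical policies are noise-limited
  at desk scale, as described above.

## A worked desk-scale example

```{r example, eval = FALSE}
cfg <- sim_config(n_women = 50000, seed = 2024)
run <- run_simulation(cfg)
totals <- cumulate(run$tallies, c(2024, 2043))
report <- scenario_report(run$tallies)
report$frontier

# and the exact accounting layer on the packaged published tables:
scenario_report(totals = load_paper_table("T2"))$frontier
```
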