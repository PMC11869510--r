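# mammosim

An individual-level microsimulation for projecting the resource impact of
revising organized breast cancer screening guidelines, written for
epidemiologists and health-policy modellers who need to compare screening
policies for women in their 40s against current practice.

## The problem

Most Canadian jurisdictions screen average-risk women with mammography every
two years from age 50 to 74. Extending organized screening to ages 40–49
detects cancers earlier — but every additional screen also produces abnormal
recalls without cancer, biopsies, and negative biopsies, and the burden lands
on the system immediately while the averted deaths accrue a decade later.
mammosim quantifies that trade-off for five policies:

| Scenario | Ages 40–49 / 45–49 | Core band |
|---|---|---|
| `SQ` | ~25% opportunistic annual uptake (high-risk women) | biennial 50–74 |
| `A40` / `B40` | organized annual / biennial, ages 40–49, from 2024 | biennial 50–74 |
| `A45` / `B45` | organized annual / biennial, ages 45–49, from 2024 | biennial 50–74 |

## The model

Each simulated woman carries a birth cohort (cohorts grow 1%/year), a risk
class (25% high-risk, onset hazard ratio 2.5), an other-cause death age from a
Gompertz-style life table (certain death by 119), and at most one tumor
history: onset from an age-specific hazard $\lambda(a)$; diameter
$d(t) = d_0 e^{rt}$ with $r \sim \mathrm{LogNormal}(\log 0.35,\ 0.5)$ per year;
node-positivity and metastasis when $d(t)$ crosses lognormal size thresholds
(ordered $d_N \le d_M$); clinical surfacing with hazard $\beta\, d(t)$; stage
from a simplified TNM lookup (T1/T2/T3 × N0/N1 × M0/M1 → 0, I–IV).

Screens fall on birthday anniversaries per the policy schedule; attendance is
certain at a program's first offer and Bernoulli(0.63) afterwards for
average-risk women. Sensitivity is logistic in $\log d$ with a penalty under
age 50; specificity is 0.93 at a first screen, 0.95 after. A positive biopsy
diagnoses the tumor at its current stage; otherwise it surfaces clinically.

Survival excludes lead-time credit by construction: with one shared quantile
$u$ per woman, the breast-cancer death age is

$$t_{\text{death}} = t_{\text{clinical surfacing}} + F^{-1}_{s(\text{detection})}(u),$$

a cure-mixture Weibull anchored at the scenario-invariant surfacing age, so
earlier detection helps only through a lower stage $s$, never through the
earlier clock start. All scenarios in a run share one population, one set of
latent histories and one set of (woman, age)-keyed draws — common random
numbers — so every reported difference is policy-induced.

The accounting layer implements the published derived statistics: cumulative
windows, differences and relative changes versus the referent
($100\,(x_{\text{alt}}-x_{\text{SQ}})/x_{\text{SQ}}$), rates per 100,000
screens, stage distributions and shifts, 2023→2024 implementation surges, and
the deaths-averted efficiency frontier. The published cumulative and stage
tables ship as checksummed CSV fixtures, and the same accounting code
reproduces the published downstream figures from them exactly.

## Worked example

Exact accounting on the packaged published totals:

```r
library(mammosim)
rep <- scenario_report(totals = load_paper_table("T2"))
attr(rep$comparisons$A40, "deaths_averted")
#> [1] 902
rep$frontier
#>    alternate additional_screens deaths_averted        slope undefined_slope
#> 1:       B45            2399021            437           NA           FALSE
#> 2:       A45            4606252            539 4.621175e-05           FALSE
#> 3:       B40            4799329            582 2.227091e-04           FALSE
#> 4:       A40            9242624            902 7.201863e-05           FALSE
```

Annual screening at 40–49 adds 9.24 M screens (+13.3%) and averts 902 deaths
over 2024–2043; the steepest frontier segment (2.2 × 10⁻⁴ deaths per screen)
lies between `A45` and `B40` — the published inflection.

A desk-scale simulation of the same five policies (50,000 women standing for
15 M, seed 2024, ~10 s):

```r
run <- run_simulation(sim_config(n_women = 50000, seed = 2024))
cumulate(run$tallies, c(2024, 2043))[
  , .(scenario, screens, recalls_no_cancer, screen_detected_dx, bc_deaths)]
#>    scenario  screens recalls_no_cancer screen_detected_dx bc_deaths
#> 1:       SQ 44076300           2253000             167400     37500
#> 2:      A40 52127400           2678400             170400     37200
#> 3:      B40 48614100           2503200             170100     37500
#> 4:      A45 48159000           2467500             169800     37200
#> 5:      B45 46722000           2397900             168900     37200
```

Counts are weighted persons. The simulator is a documented stand-in for the
proprietary calibrated platform behind the published totals: orderings,
identities and surge patterns are meaningful; absolute counts are not meant to
match (see the vignette in `vignettes/screening-scenarios.Rmd`).

## Analysis workflow

Numbered drivers under `analysis/` run the full study and write everything
under `results/`:

1. `01_reproduce_published_tables.R` — exact accounting from the packaged tables;
2. `02_simulate_scenarios.R` — coupled five-scenario run (200,000 women by
   default; `MAMMOSIM_N`/`MAMMOSIM_SEED` override);
3. `03_compare_scenarios.R` — comparison report, rates, stage shift, surge,
   frontier from the simulated tallies;
4. `04_figures.R` — figures (additional outcomes, frontier, stage mix, annual
   recall trajectory).

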