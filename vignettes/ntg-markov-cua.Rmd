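---
title: "A Markov cohort cost-utility model for normal-tension glaucoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for normal-tension glaucoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntgcua)
```

## The decision problem

Normal-tension glaucoma (NTG) is glaucomatous optic-nerve damage and visual
field loss occurring at intraocular pressures (IOP) in the normal range.
Lowering IOP by about 30% from baseline slows progression, and two broad
management policies compete for patients diagnosed at the mild stage:

* **Traditional management** — observation with regular follow-up while the
  disease is mild; trabeculectomy (filtration surgery) with postoperative
  care once the disease reaches the moderate or severe stage.
* **Positive treatment** — intensive IOP lowering from the mild stage
  onwards: dual or triple topical therapy for everyone, with a configurable
  fraction of patients undergoing trabeculectomy immediately at entry.

`ntgcua` implements the decision-analytic Markov cohort model that compares
these policies over a 10-year horizon for a Chinese cohort entering at age
64, and reports the incremental cost-utility ratio (ICUR) judged against
willingness-to-pay thresholds of one and three times China's GDP per capita
($12,692.90).

## Model structure

The cohort occupies four states — mild, moderate, severe, dead — and moves
between them in annual cycles. Within a cycle a patient can stay, progress
one severity stage, or die; death is absorbing, regression and stage
skipping are excluded. Disease severity maps to preference weights
(utilities) of 0.80, 0.75 and 0.71 per year in the mild, moderate and
severe stages, and 0 when dead; quality-adjusted life years (QALYs) are
utility-weighted, discounted life years.

### Transition probabilities

Annual progression probabilities are strategy specific: 0.044 (mild to
moderate) and 0.018 (moderate to severe) per year under positive treatment,
versus 0.149 and 0.056 under traditional management. The treated
mild-to-moderate figure is consistent with the 5-year progression
probability of 20% observed under a sustained 30% IOP reduction: with a
constant hazard, `prob_to_rate(0.20, 5)` gives 0.0446 events per
person-year and `rate_to_prob(0.0446, 1)` returns an annual probability of
0.0436, i.e. about 4% per year. (The survival form `exp(-rate * t)` gives
the probability of *not* progressing; the package uses the event
probability `1 - exp(-rate * t)`, which is what the 4% figure requires.)
An alternative preset, `parameter_preset("alternative_rates")`,
carries the steeper visual-field-slope-derived annual rates of 8.5%/3.5%.

### Mortality

Background mortality is age banded: 0.364% per year at ages 65–69 and
0.518% at 70–74. Glaucoma of any stage multiplies the *odds* of death by
1.8 (`adjust_mortality()` converts probability to odds, multiplies, and
converts back — the input is explicitly an odds ratio, so the adjustment
stays on the odds scale). Each model cycle uses the band of the age
attained at the *end* of that cycle: the cohort enters at 64, so its first
year of exposure is the risk of dying by 65, which the first band covers;
cycles 0–4 therefore use the 65–69 band and cycles 5–9 the 70–74 band.
Mortality does not differ by disease stage.

### Event composition within a cycle

Progression and death are treated as mutually exclusive competing events
within one annual cycle: from an alive state with progression probability
`p` and death probability `q`, the row is `(1 - p - q, p, q)` over (stay,
progress, die). This additive composition keeps every row exactly
stochastic (the engine verifies `p + q <= 1`, comfortably true at these
magnitudes) and corresponds to the usual spreadsheet formulation of annual
cohort models. The alternative — applying death first and progression to
survivors, `(1-q)(1-p)` — changes 10-year QALYs only in the third decimal,
but the additive form is the convention this model's published accounting
is calibrated to (see *Accounting conventions*).

## Accounting conventions

Cost-utility results from annual-cycle models are sensitive to a small set
of accrual conventions. The set used here, chosen once and applied to both
arms identically, is:

* **Benefits.** Each cycle's QALY contribution uses *mid-cycle* occupancy —
  the mean of the cycle-start and cycle-end state distribution — dotted
  with the utilities. This is the half-cycle correction: members who
  transition during a year are credited with half a year in each state.
* **Recurring costs** use the *end-of-cycle* occupancy: expenditure follows
  the state reached, since a progression event triggers the corresponding
  care (escalated medication, stage-entry costs) in the year it is
  observed.
* **Discounting.** Both costs and QALYs are discounted at 3.5% per year
  with the cycle-start weight `(1 + r)^-k` for cycle `k` (cycle 0
  undiscounted). `discount_factor()` also offers the half-cycle-shifted
  exponent `(1 + r)^-(k + 0.5)` for users who prefer that variant, but the
  engine keeps the half-cycle correction in the occupancy instead.
* **One-time outlays.** The trabeculectomy cost of the positive arm's
  surgical path is billed at model entry with weight 1/2 under the
  half-cycle correction — the lump-sum analogue of crediting flows at
  mid-cycle. (With `half_cycle_correction: false` both the occupancy
  averaging and the half weight are switched off.)

With these conventions the model reproduces the published per-person
discounted outcomes of the underlying Chinese NTG analysis — 6.58 QALYs
(positive) and 6.43 (traditional) — at two-decimal precision, and the
surgery-cost-multiplier scenarios to within a fraction of a percent.

## Costing rules

Unit costs (2023 USD): dual therapy $307.24/year, triple $470.45/year,
trabeculectomy $530.97, follow-up $79.55/year without progression and
$119.32/year after progression, traditional-arm stage costs $381.84 in the
first year of the moderate or severe stage and $254.56 in consecutive
years. Medication users split 3:1 between dual and triple therapy, so the
expected price is `0.75 * 307.24 + 0.25 * 470.45 = 348.04` per year; after
persistent progression the dosage rises 1.5-fold ($522.06). Twenty percent
of trabeculectomies fail.

**Positive arm.** The medication path pays medication plus follow-up,
escalating both once progressed. The surgical path (fraction
`surgery_rate`) pays the surgery at entry; thereafter the 80% whose surgery
succeeded accrue follow-up only, while the 20% who failed accrue
standard-dose medication plus the state's follow-up (the post-surgical
unstable-IOP regimen is the same 3:1 mix, without the escalation that
applies on the medication-primary path). Path costs blend linearly in
`surgery_rate`, so the total at any rate interpolates the all-medication
and all-surgery totals exactly — a property the tests verify cycle by
cycle.

**Traditional arm.** Mild patients accrue follow-up only. The fraction
newly entering the moderate or severe stage in a cycle — tracked on the
deterministic trace as `entrants_moderate` / `entrants_severe`, the cohort
analogue of a per-patient first-year flag — pays the stage's first-year
cost (a stage-level aggregate covering trabeculectomy and postoperative
care); later stage years pay the consecutive-year aggregate. Because those
aggregates describe the 80% whose surgery succeeded, the 20% failure
fraction of stage occupants additionally accrues long-term escalated
topical therapy (1.5 x the 3:1 mix). A member can pay a first-year cost
once per stage entered — at most twice over a lifetime (moderate, then
severe).

## Economic comparison

```{r base-case}
fit <- compare_strategies(ntg_parameters(), strategy("positive", 0.5))
fit
ce_table(ntg_parameters())
```

`icur()` reports dominance labels rather than negative ratios (a strategy
that gains QALYs and saves money is "dominant"); a zero QALY increment is
an explicit error, never a silent division. `wtp_classify()` applies the
GDP rule: below 1x GDP per capita the intervention is worthwhile, below 3x
acceptable for clinical application, otherwise not acceptable. Full
precision is kept internally; `ce_table()` rounds to the two decimals
conventional in published CUA tables. Note that tabulated ICURs in such
publications are often the ratio of *rounded* increments, so the
full-precision ratio reported here can differ from a printed one by a few
percent even when every underlying cell agrees at display precision.

## Sensitivity analysis

**One-way (tornado).** `one_way()` perturbs exactly one lever at a time,
refits the comparison, and sorts levers by the absolute ICUR spread between
their low and high settings. The default plan at a 50% surgery rate varies
surgical uptake between 25% and 50%, the positive-arm transition
probabilities by ±50%, and the eye-drop, trabeculectomy and follow-up unit
costs by ±20%. The eye-drop price, surgical uptake and mild-to-moderate
progression probability dominate the spread. The follow-up lever scales
the follow-up unit costs wherever they appear, which touches both arms;
arm-specific follow-up perturbations can be composed manually by editing a
parameter set directly.

**Probabilistic (PSA).** Parameter uncertainty is propagated by Monte
Carlo: transition probabilities and utilities are drawn from Beta
distributions and unit costs from Gamma distributions, moment matched to
mean = base value and SD = 10% of the mean (the standard assumption when
source SDs are unavailable; the original appendix distributions are not
public, so standard CEA families are used). Mortality and the odds ratio
are held fixed. Utility ordering is *not* enforced per draw — with 10%
SDs, adjacent utilities cross in a substantial minority of draws; the
result reports how often. Each draw is evaluated as a full deterministic
cohort (parameter-level uncertainty, not microsimulation), so 100,000
draws take seconds in the vectorised engine, which a test pins against
`compare_strategies()` draw for draw. The headline statistic is the ICUR
of means (mean incremental cost over mean incremental QALYs), matching how
PSA summaries are conventionally tabulated and avoiding the instability of
averaging per-draw ratios.

```{r psa, eval = FALSE}
psa <- run_psa(ntg_parameters(), strategy("positive", 0.5),
               psa_spec(100000), seed = 42)
psa
plot(psa)   # cost-effectiveness plane with 1x / 3x GDP rays
```

## Synthetic patients and cross-validation

`simulate_patients()` samples individual trajectories from the same
per-cycle matrices as the cohort engine, assigning surgery (and its 20%
failure) at entry. Its empirical state frequencies are the package's
internal oracle: the test suite requires agreement with the deterministic
trace within three binomial standard errors at every cycle and state, at
n = 200,000 in the end-to-end suite (about half a minute) and n = 50,000
in the unit tests. Patients are homogeneous at entry (all aged 64, all
mild), matching the modelled cohort; an `age_jitter` knob exists for
robustness experiments only and errors loudly if jittered ages outlive the
mortality table rather than extrapolating.

## Numerical choices and edge cases

* Occupancy conservation is enforced to 1e-9 per cycle and matrix rows to
  1e-12; probability/rate round trips hold to 1e-12.
* `prob_to_rate(1, t)` is an explicit infinite-rate error; domain
  violations in all converters name the bound.
* The mortality band lookup takes the first matching band; entry ages
  below the first band use the first band (the 64-year-old cohort's case),
  ages beyond coverage raise a configuration error.
* Equal-spread tornado rows keep their plan order (stable sort).
* `run_psa(seed =)` and `simulate_patients(seed =)` set and restore the
  global RNG state, so seeded calls are reproducible and side-effect free.
* With `sd_fraction = 0` every PSA distribution collapses to its mean and
  a single draw reproduces the deterministic result exactly.

## Problem sizes

The deterministic model is tiny (10 cycles, 4 states). Default analysis
sizes: PSA 10,000 draws interactively and 100,000 for final results
(seconds either way); microsimulation cross-checks 50,000–200,000
patients. The test suite completes in about a minute.

## Limitations

* No tunnel states: utilities and costs are state constant, so
  time-in-state effects beyond the first-year/consecutive-year split are
  not modelled.
* Direct payer costs only; no indirect or societal costs, no adherence
  behaviour, no bilateral-eye accounting.
* The traditional arm's stage aggregates fold surgery and postoperative
  medication into two numbers; they cannot be decomposed further.
* Mortality is stage independent (a single odds ratio), and the mortality
  table covers ages 65–74 only — exactly the default horizon from age 64;
  longer horizons require supplying further bands.
* The PSA's distribution families and the 10% relative SD are assumptions;
  results conditional on them should be read as fault-tolerance checks
  rather than calibrated uncertainty intervals.
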