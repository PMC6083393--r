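---
title: "A Markov cohort model of risk-based breast cancer screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of risk-based breast cancer screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcscreen)
```

## The decision problem

Urban Chinese screening programmes invite women aged 40–69, identify a
high-risk subgroup by questionnaire, and offer them periodic breast imaging:
ultrasound with mammographic follow-up at ages 40–44, combined ultrasound and
mammography at 45–69, with biopsy confirmation of any suspicious finding.
`bcscreen` asks whether that programme buys enough health, at the prices the
programme pays, to justify its cost against a no-screening comparator — the
standard cost–utility question, answered with a Markov cohort state-transition
model run from age 40 to age 100.

The model follows a cohort of high-risk women (relative risk of onset 2
versus the general female population, applied in both arms) through seventeen
health states: healthy; preclinical ductal carcinoma in situ (DCIS);
preclinical (undiagnosed) invasive stages I–IV; treated DCIS and treated
stages I–IV; diagnosed-but-untreated stages I–IV (used only when treatment
uptake is below 1); and two absorbing death states (breast-cancer death,
other-cause death).

## Natural history

Healthy women acquire invasive disease at age-band-specific annual onset
probabilities scaled by the high-risk relative risk, or DCIS at a fixed ratio
(0.12) of the invasive onset probability. DCIS progresses to invasive stage I
at 2.02 times the invasive onset probability. Undiagnosed invasive disease
advances I→II→III→IV at annual probabilities 0.06, 0.11, 0.15; only stage IV
kills (0.23 per year untreated). Undiagnosed cases surface through
symptomatic presentation at stage-specific annual probabilities (0.004,
0.014, 0.380, 0.980 at baseline — themselves the product of calibration, see
below). Once treated, a case no longer progresses between stages; its only
breast-cancer hazard is the stage-specific post-treatment fatality rate
(0.006, 0.042, 0.093, 0.275 per year). Other-cause mortality applies to every
living state at the life-table rate.

### Event order within a cycle

The cycle length is one year with no half-cycle correction (the plain cohort
default; a switchable correction was considered and rejected as it changes
nothing about comparisons between arms sharing the convention). Within a
cycle, events fire in a fixed order, each conditioned on the earlier events
not having fired:

1. other-cause death,
2. breast-cancer death,
3. the scheduled screening round, if due,
4. symptomatic presentation,
5. onset and stage progression (invasive onset drawn before DCIS onset for
   healthy women; progression applied simultaneously from the pre-step
   occupancy).

Sequential conditioning keeps every transition row exactly stochastic without
renormalisation, which the test suite verifies to 1e-12 for all ages and for
randomly drawn parameter sets. Survivors of the cycle then accrue one year of
state utility, discounted to age 40 at the annual discount rate (3% for both
costs and QALYs at baseline). Costs are charged in the cycle they occur:
questionnaire and imaging per attended round, biopsy per positive screen
(true or false), and the one-time stage-specific treatment cost at diagnosis.

### Utilities

Stage utilities (0.79, 0.79, 0.77, 0.69 for stages I–IV) attach to the
disease stage itself, whether or not the cancer has been diagnosed; healthy
women and in-situ disease (DCIS, treated or not) carry utility 1. This was a
genuinely open design choice and the most consequential one in the package.
The alternative — utility 1 for undiagnosed preclinical disease on the
grounds that the woman is unaware — makes early detection a pure utility
penalty: screening moves women from utility 1.0 to 0.79 for decades, the
screening arm loses of the order of 0.1 QALYs per woman, and screening is
dominated under every other assumption we tried. That inverts the
qualitative behaviour a screening cost-utility model must reproduce (earlier
detection yields more QALYs through lower stage-specific fatality). Reading
the utility as a property of the disease stage restores the expected
direction and leaves the two arms differing only through stage composition
and survival, which is what stage-specific EQ-5D utilities measure.

### False-positive episodes

A disease-free woman screens falsely positive with probability
1 − specificity, proceeds to biopsy, and experiences a 25% utility decrement
(range 0.11–0.34) for the duration of the episode. The duration is not part
of the published parameter set. We model it as a five-week episode
(`fp_duration_years = 5/52.18`, exposed in the configuration): the decrement
derives from short-term distress measured around recall and resolves with a
benign biopsy result. Applying it for a full model cycle instead would make
false-positive disutility the single largest QALY driver in the model
(≈ 0.08 QALYs per woman under annual screening, several times the entire
mortality benefit) and would make *less* screening always better — again
inverting the direction the model exists to quantify.

## Screening

Eligible ages are screened every `interval_years` years starting at the lower
eligible age. Test sensitivity and specificity are those of the modality
combination mapped to the woman's age band (0.848/0.994 for
ultrasound-then-mammography at 40–44; 0.939/0.980 for
ultrasound-plus-mammography at 45–69). Attendance is 100%; biopsy is treated
as perfectly accurate; all biopsy-confirmed invasive cases move to the
treated state (or, with probability 1 − `treatment_uptake`, to
diagnosed-untreated, which keeps untreated progression and fatality, accrues
stage utility, and incurs no treatment cost). A DCIS case declining treatment
simply remains in the DCIS state. Mammography-alone performance is not part
of the bundled defaults; supplying a `mammo_alone` entry in `test_perf`
unlocks the modality-comparison scenarios in `run_scenarios()`.

## Calibration

In the unscreened arm cases surface only through symptoms, so the stage
distribution at presentation is determined jointly by the progression rates
and the per-stage symptom probabilities. `calibrate_symptom_probs()` recovers
the symptom probabilities from a target stage distribution (e.g. a cancer
registry's reported distribution of incident cases) by Nelder–Mead simplex
search on the logit scale, minimising the L2 distance between the model's
presentation distribution and the target, with a fixed start point so the
result is deterministic. The baseline symptom probabilities ship as defaults,
so calibration is optional. Note the objective has a mildly flat direction:
stage-IV presentation competes with stage-IV death, so very high stage-IV
symptom probabilities are weakly identified; round-trip recovery is within a
few percent for the baseline vector and within the stated tolerance in
distribution space for arbitrary vectors.

## Economics and uncertainty

`compare_strategies()` reports incremental discounted cost and QALYs, the
ICER, net monetary benefit at the willingness-to-pay threshold (US$ 23 050
per QALY, three times 2014 GDP per capita), and a dominance classification;
for trade-off comparisons the threshold rule is positive net monetary
benefit. One-way analyses (`one_way()`, `tornado()`) re-evaluate both arms at
a parameter's published minimum and maximum. The probabilistic sensitivity
analysis (`run_psa()`) draws every parameter that carries a range — test
performance (beta), utilities and the false-positive disutility (log-normal),
and costs (gamma) — and re-runs both arms per draw; transition probabilities
and incidence, published without ranges, stay fixed. Distributions are fitted
by pinning the mean at the baseline and deriving the spread from the
(min, max) read as an approximate central 95% interval
(`sd = (max − min)/3.92`), then moment-matching within the family. Pure
quantile matching was rejected because it cannot simultaneously hold the mean
at the baseline (for the combined-modality sensitivity it displaces the mean
by over 1%), and a mean-preserving fit is what keeps the PSA centred on the
deterministic base case. Draw order is fixed by sorted parameter path, so a
seed fully determines a PSA.

## The synthetic life table

Other-cause mortality (all-cause minus breast-cancer mortality) must be
supplied as a `bc_life_table`. For testing and worked examples the package
generates a synthetic Gompertz schedule,
`h(a) = level · exp(slope · (a − 40))`, integrated over each year of age. The
defaults (level 9e-4, slope 0.10 per year) were chosen on demographic
grounds to emulate adult female mortality in urban China — a hazard of about
0.9 per 1000 at age 40, doubling roughly every 7 years, giving a remaining
life expectancy at 40 of about 41 years. A Gompertz curve is smooth where
real national schedules wobble, has no accident hump, and does not subtract
cause-specific breast-cancer mortality; results computed on it are
internally consistent but not a substitute for a transcribed national life
table, which should be supplied via `bc_life_table()` for any applied use.

## The microsimulation oracle

`simulate_cohort()` is an individual-level Monte-Carlo re-implementation of
the identical model: it shares the parameter and strategy objects and the
event-order convention, but samples each woman's history directly and never
touches the transition-matrix or occupancy-vector code. Agreement between
the two engines — means within three standard errors at 200 000 women, both
arms, at baseline and at five randomly drawn parameter sets — is the
package's central correctness property, checked in the test suite. The
problem sizes used there (200 000 women for the oracle comparison, 1 000 PSA
draws, 61 annual cycles) are the package's reference study conditions.

## Known limitations

- Treated cases never relapse or progress; their only breast-cancer hazard
  is the constant post-treatment fatality rate, so early treatment confers a
  lifelong hazard reduction rather than a cure fraction.
- DCIS is detectable only by screening and never presents symptomatically.
- Screening attendance is fixed at 100%; only treatment uptake varies. With
  costs charged per attended round, programme costs scale linearly with
  rounds offered, and the cost side of the model therefore sits well above
  what a partial-attendance programme would spend.
- Stage-specific test sensitivity, radiation harms, and overdiagnosis beyond
  the DCIS state structure are not modelled.
- The high-risk relative risk (2) multiplies general-population incidence in
  both arms; whether the comparator should instead be general-population risk
  is exposed as the `high_risk_comparator` flag.

## Worked example

```{r example, eval = FALSE}
params <- load_parameters(system.file("extdata", "params_table1.yaml",
                                      package = "bcscreen"))
lt <- synthetic_life_table()
annual <- run_cohort(bc_strategy("annual", 1), params, lt)
none <- run_cohort(no_screening(), params, lt)
compare_strategies(annual, none, params$wtp_threshold)
run_scenarios(params, lt)
```
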