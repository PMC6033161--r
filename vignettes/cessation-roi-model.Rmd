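---
title: "A Markov cohort model for the economics of smoking cessation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the economics of smoking cessation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitroi)
```

## The model

`quitroi` forecasts what a decision-maker buys when they fund smoking
cessation: the lifetime healthcare costs, life-years and QALYs of smokers
who quit within the next twelve months, against those of smokers who do
not, and the cost per QALY gained of intervention packages that shift the
balance between the two groups.

The engine is a three-state Markov cohort model with an annual cycle:
*current smoker*, *former smoker* and *dead*, death absorbing. Two
deterministic cohorts are run for every entry age and sex: one in which the
whole cohort quits during the first cycle (it enters the former-smoker
state immediately) and one in which it does not (it enters as current
smokers). A package's first-cycle quit probability then mixes the two
cohorts; nothing stochastic happens inside the cohorts themselves. Cohorts
are replicated for every entry age from `entry_age_min` (16 by default, 18
where national surveys start there) to 85 and both sexes, run until age
100, and averaged with weights proportional to the number of current
smokers in each age–sex stratum.

Each cycle a cohort faces status-specific mortality evaluated at its
attained age, and surviving current smokers move to the former-smoker
state with the *net* quit probability — an annual rate (about 2% in most
western European smoking populations, 1% in Hungary) that already balances
cessation against relapse and late initiation, which is why relapse is not
modelled as a separate flow. The transition is applied at the end of every
cycle, so it shapes occupancy from cycle 2 onward while the first-cycle
status remains fixed by the scenario.

### Status-specific rates from population data

National statistics give the *population* probability of death and the
*population* prevalence of each disease, not the rates for smokers. The
model recovers status-specific values by the standard
population-attributable decomposition: with status proportions
$\pi_n, \pi_f, \pi_c$ and relative risks $RR_f, RR_c$ (former and current
versus never smokers),

$$p_{never} = \frac{p_{all}}{\pi_n + \pi_f RR_f + \pi_c RR_c},\qquad
p_{former} = RR_f\, p_{never},\qquad p_{current} = RR_c\, p_{never},$$

so that the status-prevalence-weighted mean reproduces $p_{all}$ exactly.
The same linear decomposition is applied to the prevalence of the four
tracked diseases — lung cancer, coronary heart disease, COPD and stroke —
with relative effects interpreted as prevalence ratios (the sources state
relative effects without committing to an odds scale, and the prevalence
ratio keeps the decomposition linear and exactly consistent). Below age 35
disease risk is taken as equal across smoking statuses: differential rates
are not observed there and absolute prevalence is tiny, so the assumption
is conservative and nearly inconsequential. Mortality relative risks apply
at all ages. Any probability pushed above 1 by the scaling is capped at 1
with a warning rather than allowed to crash a run on extreme synthetic
inputs; capping breaks the exact-reconstruction identity for that cell
only.

Former smokers carry a single average risk: the model does not adjust for
time since quitting, because distributional data on quit duration are not
generally available. In a cohort (rather than individual-level) model the
aggregate impact of this simplification is limited, but it means early
years after cessation are somewhat too optimistic and late years somewhat
too pessimistic.

### First-cycle quit probability

A package couples a baseline attempt rate $A$ (share of smokers making a
quit attempt in year 1) and an unaided success probability $s_0$ with
interventions, each carrying an uptake $u_i$ among attempters, a success
relative risk $r_i$, a cost per use, an optional attempt-rate multiplier
$m_i$ and an optional fixed cost. The probability of quitting in the first
cycle is

$$q_1 = A \prod_i m_i \cdot \Big[\textstyle\sum_i u_i\, r_i s_0 +
\big(1 - \sum_i u_i\big) s_0\Big].$$

With the illustrative assumptions ($A = 0.20$, $s_0 = 0.05$) the status
quo gives $q_1 = 0.0100$; a campaign multiplying the attempt rate by 1.25
gives 0.0125; an aid with 20% uptake and $r = 1.25$ gives 0.0105.

### Costs, utilities and horizons

Per cycle, expected healthcare cost is the occupancy-weighted sum over the
two alive states of $\sum_d \text{prev}_d \times \text{cost}_d$ — costs of
prevalent cases are additive across diseases, the conventional costing
default. Utility uses the *maximum-decrement* comorbidity rule: disease
occurrences are independent, and a person with several diseases suffers
only the largest decrement. The expected decrement is therefore, with
diseases sorted by decrement descending,
$\sum_d \delta_d\, p_d \prod_{d' \prec d}(1 - p_{d'})$ — a deliberately
conservative choice relative to additive or multiplicative combination,
since it understates the QALY gains of cessation. Annual utility is the
status utility minus this expectation, floored at 0. The dead state
accrues nothing; never-smoker utilities sit in the data model for
completeness but the two scenarios only ever contain current and former
smokers.

Life-years and flows are counted at cycle-start occupancy (no half-cycle
correction; the model is a plain annual-cycle cohort design). Discounting
takes cycle 1 at face value and divides cycle $t$ by $(1+\text{rate})^{t-1}$
— with a 3.5% rate the discounted 2-year life expectancy of a healthy
cohort is $1 + 1/1.035 = 1.966$, which sits where published 2-year
discounted estimates fall relative to their undiscounted counterparts.
Outcomes are reported at 2, 5 and 10 years and lifetime (to age 100);
horizons longer than a cohort's remaining span truncate with a warning.

### Decision metrics

For a package on $n$ smokers, expected outcomes are the convex combination
$n q_1 \cdot (\text{quit outcome}) + n(1 - q_1)(\text{no-quit outcome})$
plus intervention costs
$\sum_i \text{fixed}_i + u_i \cdot nA_{\text{eff}} \cdot \text{cost}_i$.
Comparisons report incremental cost and QALYs, the ICER (reported to whole
currency units, rounded half away from zero, with unrounded arithmetic
underneath), dominance labels, net monetary benefit
$\lambda \Delta Q - \Delta C$, deaths averted, and a benefit–cost ratio.
The benefit–cost ratio has no single canonical definition; here it is
(monetised QALY gain + healthcare cost savings) / incremental intervention
spend, which makes it equal to $\text{NMB}/\Delta IC + 1$ and hence
cross-checkable against the NMB.

The worked-example interface (`england_worked_example()`) feeds published
per-smoker lifetime discounted outcomes straight into
`evaluate_package()`, so the decision arithmetic can be exercised — and
audited — without the national datasets behind them, which are not
redistributable at desk scale.

## Probabilistic sensitivity analysis

Parameter uncertainty is propagated by Monte Carlo simulation, 1000
replications by default. Distribution families follow the standard
class rules for decision models: relative risks are lognormal
(parameterised as `meanlog = log(point)`, with the stored standard error
read on the log scale — the scale on which RR uncertainty is normally
reported), status utilities are beta and disease costs gamma (both by
method of moments), utility decrements are normal (truncated at 0 when a
draw goes negative), and intervention costs and population-level data —
life tables, smoking and disease prevalence, smoker counts, the discount
rate and the net quit rate — are fixed. Sampling is of these global
parameters, not of per-age-cell noise, because uncertainty statements
attach to parameter classes, not cells. A stochastic parameter with zero
standard error degenerates to fixed with a warning; a beta standard error
incompatible with the support raises an error.

Each replicate re-derives the status-specific tables, re-runs every
cohort, re-weights and re-evaluates the packages. Reproducibility uses a
counter scheme: the master seed draws one sub-seed per replicate, and each
replicate seeds its own stream and draws all parameters in sorted-id
order, so results are invariant to parameter evaluation order and exactly
repeatable for a given `(seed, n_reps)`. Outputs are the incremental
cost–QALY scatter and the cost-effectiveness acceptability curve: at each
willingness-to-pay $\lambda$ the fraction of replicates with
$\lambda \Delta Q - \Delta C > 0$, ties counted as not cost-effective. The
default threshold grid is 0–50 000 per QALY in steps of 1 000. Expected
value of perfect information is out of scope.

## The synthetic data generator

`generate_country_dataset()` emulates the *shape* of a western European
country dataset so every stage is testable without any download: mortality
Gompertz-like in age ($p(a) = \min(1, p_0 e^{g(a - a_0)})$, anchored at
age 16 so fixtures with late entry ages share the same curve, with a male
excess factor), current-smoking prevalence declining and former-smoking
rising with age (proportions summing to 1 by construction), disease
prevalence zero before an onset age then saturating towards a plateau, and
smoker counts concentrated between ages 25 and 50 with mild lognormal
jitter, deterministic given the seed. Magnitudes are loosely calibrated so
lifetime discounted QALYs land in the 10–20 range typical of published
per-smoker estimates, making sanity checks meaningful — but the generator
makes no claim to reproduce any country's values. Real data differ in ways
the fixtures deliberately do not model: cohort effects in smoking uptake,
non-monotone disease prevalence in the oldest ages, and correlated
parameter uncertainty. Passing tests therefore demonstrate the engine's
arithmetic and invariants, not country-level predictions.

The worked-example values (England per-smoker lifetime discounted cost
9602 / 14563, QALYs 15.86 / 14.77, life-years 19.11 / 18.45 for quit /
no-quit) are carried as published inputs, not generated.

## Numerical and design choices

* First-cycle quitters are former smokers from the *start* of cycle 1,
  accruing former-smoker utility and mortality immediately; this is why a
  QALY difference is already visible at the 2-year horizon. The
  convention is isolated in the scenario initialiser of `run_cohort()` so
  the alternative (current-smoker risk during the quit year) is a
  one-line change.
* Death is evaluated against cycle-start status; the net quit transition
  applies to survivors at cycle end.
* The net quit rate is age-constant within a country; nothing in the
  sources suggests an age gradient, and an age-dependent rate would be
  straightforward to thread through `run_cohort()` if one emerged.
* Occupancy conservation holds to 1e-12 per cycle; the iterative engine
  is tested against an independent transition-matrix-power oracle at the
  same tolerance, and the decomposition against an independent linear
  solve.
* Validation tolerances: smoking-status proportions must sum to 1 within
  1e-9; file round-trips preserve reals to better than 1e-12.
* Test problem sizes: the suite runs on compact fixtures (entry ages
  60–64, and 82–84 where many replicates are needed) — large enough for
  40-cycle traces and every horizon, small enough that the full property
  suite including PSA runs in seconds.

## Limitations

The model takes a healthcare-system perspective: no productivity,
employment or social-care costs, and no unrelated healthcare costs in
added life-years (consistent with prevailing costing guidance; their
inclusion would shift all life-extending interventions by a similar
factor). Costs attach to prevalent cases annually, with no terminal-care
spike. Only four diseases are tracked — they account for roughly three
quarters of smoking-attributable deaths, so smoking's full burden is
understated. Currency is a pass-through label; no conversion or inflation
adjustment is performed. Up to three packages are compared at a time, with
no league tables or frontier analysis beyond that.
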