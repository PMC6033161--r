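# quitroi

Markov cohort return-on-investment modelling for smoking cessation.

Public-health commissioners weighing tobacco-control budgets need to know
what a package of cessation interventions buys: how many QALYs, how many
life-years, how much healthcare spending avoided, and at what cost per
QALY. `quitroi` answers this with a three-state annual-cycle Markov cohort
model — *current smoker*, *former smoker*, *dead* (absorbing) — replicated
for every entry age (16–85) and sex, run to age 100, and weighted by the
size of the smoking population in each stratum.

Two deterministic cohorts are run per stratum: quit during the first year
versus continue. Status-specific mortality and disease prevalence (lung
cancer, CHD, COPD, stroke) are recovered from population-level inputs by
the linear population-attributable decomposition

```
p_never = p_all / (pi_never + pi_former * RR_former + pi_current * RR_current)
p_former = RR_former * p_never ;  p_current = RR_current * p_never
```

so status-weighted means reproduce the population values exactly. A
package's first-cycle quit probability

```
q1 = A_eff * [ sum_i u_i * r_i * s0 + (1 - sum_i u_i) * s0 ]
```

(attempt rate × blended success across intervention users and unaided
attempters) mixes the two cohorts; comparisons report incremental costs
and QALYs, the ICER, net monetary benefit `λ·ΔQ − ΔC`, a benefit–cost
ratio and deaths averted. Parameter uncertainty is propagated by Monte
Carlo probabilistic sensitivity analysis (beta / gamma / lognormal /
normal by parameter class, 1000 replications by default) and summarised
as a cost–QALY scatter and cost-effectiveness acceptability curves.

## Worked example

Published per-smoker lifetime discounted outcomes for an average English
smoker (cost 9602 vs 14563, QALYs 15.86 vs 14.77 for quitting vs
continuing) ship with the package, together with three illustrative
interventions on a population of 2000 smokers in which 20% make a quit
attempt and 5% of unaided attempts succeed:

```r
library(quitroi)
comps <- worked_example_comparisons()
comps$attempt_boost        # campaign raising attempts by 25%, fixed cost 40000
#> <roi_comparison> attempt-rate campaign vs status quo (horizon lifetime)
#>   incremental cost 15195.00, incremental QALYs 5.4500
#>   ICER 2788 per QALY
#>   NMB at threshold 20000: 93805.00; benefit-cost ratio 3.35
comps$novel_aid            # aid: uptake 20%, success RR 1.25, 225 per attempt
#>   ICER 11962 per QALY
comps$novel_aid_promoted   # uptake doubled to 40% for a further 50000
#>   ICER 57834 per QALY
```

The campaign creates 5 extra quitters (25 vs 20), each saving 4961 in
lifetime healthcare costs and gaining 1.09 QALYs, so the 40000 outlay nets
to 15195 for 5.45 QALYs — 2788 per QALY, comfortably cost-effective at a
20000-per-QALY threshold. Doubling uptake of the novel aid buys one more
quitter for 63039 incremental spend: 57834 per QALY, not cost-effective.

A full country run needs a dataset directory (eight delimited text files:
life table, smoking prevalence, disease prevalence, relative risks,
disease costs, utilities, smoker counts, `settings.yaml`):

```r
ds  <- generate_country_dataset(fixture_params(seed = 1))  # or load_country_dataset(dir)
out <- run_scenarios(ds)               # both scenarios, all strata, weighted
sq  <- package_spec("status quo", baseline_attempt_rate = 0.2,
                    unaided_success = 0.05)
aid <- package_spec("novel aid",
         interventions = list(intervention("aid", uptake = 0.2,
                                           rr_success = 1.25,
                                           cost_per_use = 225)),
         baseline_attempt_rate = 0.2, unaided_success = 0.05)
compare_packages(evaluate_package(sq, out), evaluate_package(aid, out),
                 threshold = 20000)
reps <- run_psa(ds, list(sq, aid), n_reps = 1000, seed = 1)
ceac(reps)                             # P(cost-effective) by threshold
```

`inst/cli/roi.R` wraps the same functions for shell use
(`validate` / `run` / `psa` / `compare` / `fixture` / `worked-example`).

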