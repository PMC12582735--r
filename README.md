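# foscea

A Markov cohort cost-effectiveness model for adjunctive third-generation
antiseizure medications in pharmacoresistant focal-onset seizures, from a
healthcare-payer perspective (amounts in Jordanian dinar, JOD). The package
is written for health-economics analysts and methodologists who need a
tested, scriptable implementation of this model class: a four-state cohort
trace engine, state- and adverse-event-based costing, deterministic
incremental cost-effectiveness analysis, and a second-order Monte Carlo
probabilistic sensitivity analysis (PSA) with cost-effectiveness-plane and
acceptability-curve summaries.

## The model

Patients occupy one of four states — seizure-free (complete response, CR),
partial response (≥50% seizure reduction), non-response, discontinued —
over eight 3-month cycles (a 2-year horizon). Each treatment has constant
per-cycle outcome probabilities `(p_sf, p_pr, p_nr, p_disc)` on the unit
simplex, with non-response defined as the residual. Under the default
structure, seizure freedom and discontinuation are absorbing and partial /
non-responders re-draw each cycle, so cumulative CR after *n* cycles has
the closed form

```
CR(n) = p_sf · (1 − s^n) / (1 − s),   s = p_pr + p_nr
```

Costs accrue per cycle (drug acquisition at per-mg prices under a wastage
assumption, per-state healthcare service bundles, expected adverse-event
management) and second-year flows are discounted one year-step at 3.5%.
Effectiveness and costs feed a pairwise incremental analysis against the
reference drug (brivaracetam, BRV):

```
ICER = ΔC / ΔE        (JOD per unit CR; labelled "per 1% CR" in reports)
NMB  = λ·E − C        (λ = willingness-to-pay, JOD 9000)
```

The PSA redraws every uncertain parameter per iteration — beta
distributions moment-matched to mean/SE for probabilities (residual
non-response via rejection sampling), gamma for costs, a rescaled beta on
0–5% for the discount rate, ±25% variation read as a 95% half-width where
no SE is published — and summarizes the incremental cloud into plane
quadrants and acceptability curves. See the methods vignette
(`vignettes/markov-cea-methods.Rmd`) for every modelling decision and its
rationale.

Dose schedules are not part of the published main inputs; the packaged
defaults are synthetic label-range values, so absolute cost levels are
illustrative while the incremental worked examples below reproduce the
published figures.

## Worked example

```r
library(foscea)

cfg <- default_config()          # packaged Jordanian model inputs
run_deterministic(cfg)
#> <cea_results> deterministic base case
#>  treatment    cost effect_pct
#>        BRV 1897.08      21.83
#>        ESL 1805.67      13.28
#>        LCM 1969.47      10.98
#>        PER 2682.35      14.10
#>
#> Pairwise vs BRV (ICER in JOD per 1% CR):
#>  comparator delta_cost delta_effect_pct   icer    dominance
#>         ESL      91.41             8.56   1068 TRADE_OFF_NE
#>         LCM     -72.39            10.85   -667    SAVING_SE
#>         PER    -785.27             7.74 -10151    SAVING_SE
```

Each row is a treatment's total discounted 2-year cost and its cumulative
complete-response percentage; the pairwise block gives BRV's incremental
cost and CR gain against each comparator, the ICER, and the plane
classification (`SAVING_SE` = more effective *and* cheaper). With the
synthetic default doses BRV is cost-saving against LCM and PER and trades
off against ESL at JOD 1068 per 1% CR — well under the JOD 9000 threshold.

The published worked example (feeding the published per-treatment
cost/effect pairs into the same incremental analysis) reproduces the
published ICERs:

```r
t3 <- known_answer_cases()$table3
icer(t3$BRV, t3$ESL)
#> <incremental_result> BRV vs ESL
#>   dCost JOD -214.00, dEffect 29.01% CR, ICER JOD -738 per 1% CR [SAVING_SE]
```

PSA, plane and acceptability curve:

```r
psa <- run_psa(cfg, n_iterations = 2000, seed = 1)
round(icer_plane_quadrants(psa, "LCM"), 3)
#>    NE    SE    NW    SW
#> 0.430 0.571 0.000 0.000
ceac(psa, c(3000, 9000))
#>    wtp comparator probability
#> 1 3000        ESL      0.4835
#> 2 9000        ESL      0.7125
#> 3 3000        LCM      0.7700
#> 4 9000        LCM      0.9525
#> 5 3000        PER      0.8890
#> 6 9000        PER      0.9635
plot_icer_plane(psa, wtp = 9000); plot_ceac(ceac(psa, seq(0, 18000, 500)))
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/foscea.R --mode psa --seed 1 --iterations 2000 --out-dir results
```

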