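---
title: "Methods: a Markov cohort cost-effectiveness model for adjunctive antiseizure medications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for adjunctive antiseizure medications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foscea)
```

## The decision problem

`foscea` implements a cohort state-transition model for the economic
evaluation of adjunctive third-generation antiseizure medications —
brivaracetam (BRV) against eslicarbazepine (ESL), lacosamide (LCM) and
perampanel (PER) — in pharmacoresistant focal-onset seizures, from a
healthcare-payer perspective in Jordan (all amounts in JOD). Because
locally applicable health-state utilities are unavailable, the model is a
cost-effectiveness (not cost-utility) analysis: its effectiveness outcome
is the percentage of patients achieving complete response (CR), i.e.
seizure freedom.

## Model structure

Four mutually exclusive health states: *seizure-free* (complete response),
*partial response* (at least 50% seizure-frequency reduction),
*non-response*, and *discontinuation* (any reason). Time advances in
3-month (90-day) cycles over a 2-year horizon, so 8 cycles; the horizon
reflects the restriction of the intervention's use to two years. The whole
cohort enters treatment-naive and realizes its first multinomial outcome
at cycle 1, i.e. the first occupancy row equals the per-cycle outcome
probabilities. Occupancy is evaluated at cycle end; no half-cycle
correction is applied (none is conventional for a model whose outcome is a
cumulative response proportion rather than accrued life-years). There is
no mortality state and no post-discontinuation treatment sequencing.

The per-cycle outcome probabilities (per treatment, with standard errors)
are held constant over the horizon; the non-response probability is
defined as the residual of the other three, so each profile lies exactly
on the probability simplex. Input profiles are validated to sum to 1
within `1e-6` (printing slack is renormalized silently; larger deviations
are an error naming the treatment), and internal traces conserve mass to
`1e-12` per cycle.

### Structural variants

The source material does not state which states terminate further
transitions, and the printed cumulative CR values cannot be derived from
the per-cycle probabilities under any simple structure (see *Known
limitations*). The package therefore exposes the transition structure as
an explicit switch, `structural_variants()`:

* `absorbing_sf_disc` (default) — seizure-free and discontinued absorb;
  partial and non-responders re-draw each cycle. This matches the clinical
  reading of "discontinuation (any reason)" as leaving therapy, keeps
  complete response cumulative, and makes the reported CR the proportion
  *ever* seizure-free.
* `absorbing_disc_only` — only discontinuation absorbs; a seizure-free
  patient re-draws along with the others.
* `redraw_all` — a memoryless repeated multinomial.

Under every variant the trace also tracks `ever_sf`, the cumulative
proportion having entered the seizure-free state, via an augmented
never-yet-seizure-free mass vector; under absorbing-SF variants it
coincides with seizure-free occupancy. Three effect definitions are
available (`ever_sf`, default; `mean_sf_occupancy`; `terminal_sf`), all
proportions in [0, 1]. Under the default variant the cumulative CR has
the closed form $p_{sf}\,(1-s^{n})/(1-s)$ with $s = p_{pr}+p_{nr}$, which
the test suite uses as an independent oracle alongside an individual-level
microsimulation.

## Costing

Per cycle, three components accrue:

* **Drug acquisition** — daily dose × 90 days × per-mg cost. Cycle 1 uses
  the titration dose, later cycles the maintenance dose. Costing follows a
  wastage assumption: the full scheduled dose is charged and dose
  reductions earn no credit. The published model prices drugs per mg
  (BRV 0.042, ESL 0.004, LCM 0.013, PER 0.804 JOD/mg) but its dose
  schedules live in an inaccessible supplement, so doses are required
  configuration fields. The packaged defaults are synthetic label-range
  medians (BRV 50/100, ESL 400/800, LCM 100/400, PER 2/8 mg/day,
  titration/maintenance) and are flagged as such; absolute cost levels
  computed from them are illustrative, not reproductions.
* **Health-state services** — per trimester: seizure-free and partial
  responders have one neurologist visit (JOD 14) and an EEG (JOD 100);
  non-responders add an emergency visit (JOD 30) and one inpatient night
  (JOD 100); discontinued patients keep one outpatient visit. Bundle
  contents and counts are configurable; the "followed by outpatient
  visits" wording for non-responders is read as one visit by default.
  EEG is accrued per cycle, consistent with the per-trimester monitoring
  framing.
* **Adverse events** — annual probabilities of ataxia, dizziness, fatigue,
  nausea and somnolence are converted to per-cycle probabilities under a
  constant within-year hazard, $p_{cycle} = 1-(1-p_{annual})^{1/4}$.
  Ataxia is managed with acetazolamide, dizziness and nausea with
  cinnarizine (both priced per mg; regimens are unreported, so the default
  is a full 90-day course at common label doses — 250 and 50 mg/day —
  conservative in the spirit of the wastage assumption, and configurable);
  fatigue and somnolence receive no drug. Every event adds one GP visit
  (JOD 8). Expected AE cost accrues each cycle for the non-discontinued
  fraction of the cohort (discontinued patients are off drug and hence
  off drug-related AE risk); a first-year-only accrual is available via
  `ae_accrual = "first_year"`.

Total cost is homogeneous of degree 1 in the unit-cost vector and monotone
in every unit cost, dose and AE probability — both are tested properties.

## Discounting and incremental analysis

A year-step discount is applied to costs and effects arising in the
second model year: cycles 1–4 carry factor 1, cycles 5–8 carry
$1/(1+r)$ with $r = 3.5\%$ annual (PSA range 0–5%). This single-step rule
follows the source's description directly rather than per-cycle
compounding.

Pairwise incremental analysis is strictly against the reference treatment
(BRV): $\Delta C = C_{BRV} - C_{comp}$, $\Delta E$ likewise on the CR
proportion scale, ICER $= \Delta C / \Delta E$. Reports label the ICER
"JOD per 1% CR", mirroring the field's labelling convention for this
model even though the denominator is the proportion difference — the only
convention under which the published worked-example ICERs (−737, 2744,
−6113) are recovered from the published cost/effect pairs. Dominance is
classified by quadrant: `SAVING_SE` (more effective, cheaper),
`TRADE_OFF_NE`, `DOMINATED`, `TRADE_OFF_SW`; a zero effect difference is
an explicit error condition carrying the cost-difference sign. Net
monetary benefit is $\lambda E - C$; at a willingness-to-pay threshold
$\lambda$ on the matching scale, $\Delta NMB > 0 \iff ICER < \lambda$
for $\Delta E > 0$ (tested). The threshold is JOD 9000 (three times GDP
per capita).

## Probabilistic sensitivity analysis

A second-order Monte Carlo with 2000 iterations by default. Per
iteration, independently:

* transition probabilities: beta distributions moment-matched to mean and
  SE ($k = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu k$,
  $\beta = (1-\mu)k$); seizure-free, partial-response and discontinuation
  are drawn, non-response is the residual, and draws with a negative
  residual are rejected and redrawn (cap 1000, then an error naming the
  treatment) — accepted draws always lie on the simplex;
* drug and AE-management per-mg costs: gamma, $shape = \mu^2/\sigma^2$,
  $scale = \sigma^2/\mu$;
* service unit costs: gamma, with the stated ±25% variation read as a 95%
  interval half-width, $\sigma = 0.25\,\mu/1.96$;
* annual AE probabilities: beta with the same ±25% convention (no SE is
  reported for them; this mirrors the cost-variation convention and is
  exposed as `ae_prob_variation_pct`);
* discount rate: a beta moment-matched on the unit interval and affinely
  rescaled to the stated 0–5% range, mean 3.5%, default SE one quarter of
  the half-range (0.625 percentage points) — honouring both the stated
  family and the stated range.

Dose schedules are not varied (no uncertainty is reported for them).
Parameters are sampled independently; the source states no correlation
structure. A zero-SE configuration degenerates every sampler to its mean,
so the PSA reproduces the deterministic pipeline bit-for-bit — a tested
invariant, as is bit-identical reproducibility under a fixed seed.

Plane summaries classify each iteration's $(\Delta E, \Delta C)$ into the
four quadrants; boundary points follow a documented tie rule
($\Delta C = 0$ counts toward the cost-saving side, $\Delta E = 0$ toward
the non-effective side; both configurable). The CEAC reports, per
threshold and comparator, the fraction of iterations with positive
incremental NMB on the CR-proportion scale.

## Synthetic instances and the validation oracle

`generate_model()` produces fully valid synthetic configurations:
transition profiles from a symmetric Dirichlet (concentration 8 by
default, keeping residual non-response probabilities comfortably
positive), SEs as a fixed fraction of the binomial bound
$\sqrt{p(1-p)}$, log-uniform per-mg drug costs spanning the study drugs'
range (0.004–0.8 JOD/mg), uniform service costs and AE probabilities. The
generator emulates the *statistical shape* of the real inputs — simplex
profiles with small SEs, positively skewed costs, annual AE risks — but
not their clinical correlations (e.g. more effective drugs tending to
cost more), so passing tests on synthetic instances demonstrate engine
correctness, not clinical realism.

`microsim_oracle()` is the independent brute-force check: it simulates
individual patients through the same structural variant and returns
empirical occupancy and ever-seizure-free frequencies with binomial
standard errors. The validation battery compares the cohort expectation
against a 100,000-agent microsimulation within 3 binomial SEs per state
per cycle, checks sampler moments against 100,000 draws, and runs the
degenerate 2000-iteration PSA equivalence; these problem sizes keep the
whole battery at a few seconds while leaving Monte Carlo error far below
the tolerances.

## Numerical choices

* Input simplex tolerance `1e-6` (silent renormalization below, error
  above); trace conservation asserted to `1e-12`.
* Beta moment-matching requires $\sigma^2 < \mu(1-\mu)$; violations are
  an explicit infeasible-moments error, and $\sigma = 0$ is a degenerate
  flag (samplers return the mean). Probability means of exactly 0 or 1
  are treated as certain.
* Reports round JOD to 2 decimals and ICERs to whole JOD; iteration-level
  CSVs keep full precision.

## Known limitations

* The published absolute cost and effect levels (e.g. BRV JOD 3925,
  57.71% CR) are **not** reproducible from the main published inputs: the
  dose schedules are unavailable and the effect-generating structure is
  under-specified — none of the three implemented variants yields 57.71%
  from a 0.065 per-cycle seizure-free probability (the default variant
  gives ≈21.8% cumulative CR). The package does not tune toward those
  numbers; it reproduces the published *incremental* worked examples
  (ICERs and CR gains from the printed cost/effect pairs) exactly, and
  reports its own computed levels transparently.
* Payer perspective only: no productivity or patient-time costs, no
  adherence, no treatment sequencing after discontinuation, no mortality.
* AE management regimens and the AE-probability uncertainty are package
  conventions (documented above), not published values.
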