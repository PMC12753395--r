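---
title: "Methods: a three-state Markov cohort model for surgical cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cohort model for surgical cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcea)
```

## The decision problem and the model

pdcea compares two surgical strategies for resectable pancreatic ductal
adenocarcinoma — open (OPD) versus laparoscopic (LPD)
pancreaticoduodenectomy — on cost per quality-adjusted life year (QALY).
Disease history after surgery is collapsed into three mutually exclusive
health states: disease-free survival (DFS), progressed disease (PD) and
death (D). Every simulated patient starts in DFS; each monthly cycle a
patient either stays, progresses, or dies, with progressed patients able
only to remain progressed or die (no return to DFS) and death absorbing.
The default horizon is 120 monthly cycles (10 years), long enough that
essentially the whole cohort is absorbed: pancreatic cancer progresses
quickly, which is also why a monthly rather than yearly cycle is used.

### From medians to monthly probabilities

The only survival inputs are each arm's median DFS and overall survival
(OS) in months. Under a constant-hazard (exponential) assumption the
monthly probability of an event with median time-to-event $m$ is

$$p \;=\; 1 - 0.5^{1/m} \;=\; 1 - e^{-R}, \qquad R = \ln(2)/m ,$$

implemented in `monthly_risk()` (with `rate_to_prob()`/`prob_to_rate()`
exposing the exact rate–probability round trip). `build_transition_matrix()`
assembles a strategy's matrix from its two medians:

* DFS → PD from the DFS median,
* DFS → D from the OS median,
* PD → D from the post-progression median, taken as `median_os - median_dfs`,
* stay probabilities as row residuals; death is absorbing.

Two conventions here deserve comment, because the design was genuinely
open. First, using the OS median directly for DFS → D slightly
double-counts the death hazard against DFS exit (the OS median describes
death from any state, not death from DFS). We keep that convention as the
default because it is the one under which the published probability table
is reproduced exactly from the medians alone; a strict competing-risks
variant — DFS exit hazard set by the DFS median and split between
progression and death in proportion to rates — is available via
`method = "competing-risks"`. Second, the post-progression median as the
difference of the OS and DFS medians is the unique rule that reproduces
the published PD → D entries (22 − 14 = 8 months → 0.083/month;
24 − 15 = 9 → 0.074), so it is adopted and documented rather than treated
as an estimate.

Probabilities are kept at full precision internally. The reporting table
(`transition_table()`) rounds *exit* probabilities to three decimals and
reports stay probabilities as complements of the rounded values, which is
how such tables are conventionally printed and keeps the printed rows
internally consistent; sensitivity bounds (±20%, capped at 1) are computed
from the rounded baselines for the same reason. Traces always use the
unrounded matrix.

A degenerate-input guard: when `median_os - median_dfs` falls below half a
cycle the PD → D monthly probability exceeds 0.75 and the monthly
discretisation becomes coarse; the constructor warns rather than errors.

### The cohort trace and half-cycle correction

`run_trace()` tracks cohort membership at cycle boundaries
(`n_cycles + 1` rows starting from everyone in DFS) by repeated
vector–matrix multiplication. State transitions in reality occur
throughout a cycle, not at its end, so per-cycle occupancy is accrued with
the half-cycle correction as the trapezoid of consecutive boundary
memberships, $(m_t + m_{t+1})/2$. The correction is applied to both cost
and utility accrual (the convention when only one accrual rule is stated);
`half_cycle = FALSE` switches to end-of-cycle accrual for comparison. No
forced absorption is applied at any cycle: the cohort reaches death
through the transition probabilities themselves, and by cycle 120 the
surviving fraction under the default parameters is below 2%.

The engine is validated two independent ways in the test suite: against
explicit matrix powers (exact to 1e-10) and against a patient-level
microsimulation oracle (`microsim_oracle()`, 200,000 simulated patients
agree with the cohort trace within binomial sampling error, max absolute
deviation < 0.005).

### Economics

Costs and utilities follow a deliberately minimal accrual structure:

* a one-time initial (surgical admission) cost at cycle 0, undiscounted;
* a uniform per-cycle cost while alive;
* per-cycle QALYs $d(t)\,(occ_{DFS}\,u_{DFS} + occ_{PD}\,u_{PD})/12$ —
  the division by 12 converts person-months weighted by annual utilities
  into QALY-years;
* death carries zero cost and utility;
* compound annual discounting at rate $r$ (default 5%/year) applied from
  cycle 1 with per-cycle factor $d(t) = (1+r)^{-t/12}$, so cycle 12
  discounts by exactly one year.

The incremental cost-effectiveness ratio is
$\mathrm{ICER} = (C_1 - C_2)/(U_1 - U_2)$, compared against a
willingness-to-pay (WTP) threshold of 268,074 yuan/QALY (three times 2023
Chinese per-capita GDP). `icer()` implements the full decision lattice
(cost-effective / not / dominant / dominated, with the reversed
interpretation when both increments are negative), and `nmb()` provides
net monetary benefit, whose pairwise difference changes sign exactly at
the ICER — the identity the probabilistic analysis relies on.

**Calibration instead of irreproducible totals.** The published cumulative
totals for this comparison (about 2.2–2.3 QALYs and 2.8× the per-patient
direct cost) are not reachable from the stated survival, utility and cost
parameters by a standard trace — a direct computation yields materially
lower QALYs (about 1.1–1.2), and the accrual convention behind the
published totals is unstated. The package therefore does not pretend to
re-derive them: cumulative cost totals are treated as *calibration
targets*. Because accrual is exactly linear in the per-cycle cost,
`calibrate_state_costs()` solves for the per-cycle alive cost in closed
form, and re-evaluation reproduces the target to numerical precision.
Published QALY totals are handled as worked-example inputs through
`econ_result()`, from which the incremental arithmetic (ΔC = 13,175.31;
ΔU = 0.064; ICER = 205,864.22/QALY, below WTP) is recomputed exactly. The
incremental effect is taken as the unrounded difference of the printed
totals (0.064), which is the value consistent with the printed ICER; the
separately printed 0.063 is a rounding artifact.

### Sensitivity analyses

`one_way_tornado()` varies one parameter at a time over baseline ±20%
(probabilities and utilities capped at 1; costs uncapped; the shared
discount rate included), re-runs the full pipeline at each bound and
reports the ICER range, sorted by span. Perturbing a transition
probability re-derives the same-row stay probability as the residual, so
rows remain stochastic. Under the calibrated baseline configuration the
direct-cost parameters dominate the tornado, with transition
probabilities, utilities and the discount rate contributing less — the
qualitative pattern expected when the cost difference between arms is the
main driver of the ICER.

`psa()` is a 1,000-draw Monte Carlo re-evaluation. No parameter
distributions are published for this comparison, so the default samples
each parameter independently and uniformly on its ±20% range — the only
dispersion information available; moment-matched beta (probabilities,
utilities) and gamma (costs) alternatives are available via
`distributions = "beta-gamma"`. Draws whose perturbed DFS row would exceed
total probability 1 are resampled (hard cap 100 attempts). The discount
rate is excluded from the PSA by default (no published range) but included
in the tornado. Given a seed the PSA is bit-reproducible. `ceac()` turns
the draw set into a cost-effectiveness acceptability curve — at each WTP
on a 0–400,000 grid (10,000-yuan steps, spanning the 50,000 / 200,000 /
268,074 landmarks), the exact fraction of draws with positive incremental
net monetary benefit.

One property worth stating precisely: with symmetric sampling the CEAC
crosses probability 0.5 at the *median* of the per-draw cost increments
over the effect increment. That median equals the deterministic ICER when
the sampled parameters enter the increments linearly (costs), and the test
suite asserts the crossing there; for the full parameter set the ICER is a
nonlinear ratio of the draws and the crossing can sit well away from the
deterministic value, so no such assertion is made — or should be expected —
for the full PSA.

## The synthetic cohort generator

`generate_cohort()` emulates the retrospective two-arm cohort the analysis
assumes, closing the loop for parameter-recovery testing:

* latent DFS times exponential at the arm median (DFS is the composite
  progression-or-death endpoint, matching its standard definition);
* post-progression survival exponential and independent of the DFS time;
* overall survival as their sum;
* administrative censoring only: entry uniform over a 45-month accrual
  window with a single cutoff at month 87 (the follow-up design of the
  emulated study: 45 months of accrual, telephone follow-up to about 3.5
  years after the last entry), no loss to follow-up;
* per-patient direct costs log-normal at the arm mean with coefficient of
  variation 0.3 — positive and right-skewed, typical of hospital cost
  data; no dispersion is published, so the CV is a fixed package default.

The sum of two exponentials is hypoexponential, and its median is *not*
the sum of the component medians — configuring the post-progression
median as `median_os - median_dfs` would inflate the latent OS median by
roughly three months. The generator therefore solves the post-progression
median from the hypoexponential median equation
(`pps_median_for_os()`; for the 14/22-month arm the solved value is 5.09
months) so that the latent OS median equals the configured arm OS median.
An explicit `median_pps` can still be supplied to override this.

What the generator does *not* emulate: covariates (age, sex, stage,
differentiation), group imbalance or matching, the published hazard
ratios between arms (only the medians are targeted), non-exponential
hazards, loss to follow-up, and any cost–survival correlation. Passing
parameter-recovery tests therefore demonstrates that the estimation
pipeline (Kaplan–Meier medians via the survival package, arithmetic cost
means) is consistent for data satisfying the model's own assumptions — not
that real surgical cohorts satisfy them.

## Numerical choices and problem sizes

Tolerances: row-stochasticity is enforced at 1e-12 on construction and
1e-8 on input validation; trace conservation is tested at 1e-10 over 120
cycles; calibration round-trips at 0.01 currency units; the
rate–probability round trip at 1e-12. Monetary output is rounded to 2
decimals, probabilities to 3, only at reporting.

The shipped configurations and tests use the study-scale problem sizes:
120 cycles, 1,000 PSA draws, 100 patients per arm for the demonstration
cohort, 10,000 per arm for parameter-recovery checks, and 200,000
simulated patients for the microsimulation validation; these sizes keep
Monte Carlo error comfortably inside the asserted tolerances.

## Known limitations

* Constant hazards throughout: no cure fraction, no time-varying risk,
  no tunnel states or age-dependence.
* The cost-accrual structure (initial + uniform alive cost) is the minimal
  identifiable one given a single cumulative target per arm; a per-state
  cost split is supported in configuration but has no published values
  behind it.
* PSA distributions are assumptions (uniform on ±20% ranges), not
  published uncertainty; CEAC probabilities inherit that assumption.
* The published between-arm hazard ratios are not reproduced by the
  generator, which targets medians only.
* Utilities come from external sources for a different population than
  the emulated cohort; the model treats them as fixed inputs.
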