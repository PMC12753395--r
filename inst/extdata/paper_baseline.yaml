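# Baseline two-strategy configuration: open (reference) vs laparoscopic
# (comparator) pancreaticoduodenectomy. Medians in months, costs in 2023 RMB.
# Per-cycle alive costs are calibrated at load time so each strategy's
# discounted cumulative cost reproduces its target total.
n_cycles: 120
wtp: 268074.00
discount: 0.05
half_cycle: true
reference:
  label: OPD
  median_dfs: 14
  median_os: 22
  u_dfs: 0.792
  u_pd: 0.650
  initial_cost: 95994.18
  target_total_cost: 269164.88
comparator:
  label: LPD
  median_dfs: 15
  median_os: 24
  u_dfs: 0.810
  u_pd: 0.650
  initial_cost: 100013.20
  target_total_cost: 282340.19
sensitivity:
  fraction: 0.20
  n_draws: 1000
  seed: 1
  distributions: uniform
cohort:
  n_per_arm: 100
  cost_cv: 0.3
  accrual_window: 45
  followup_cutoff: 87
# published cumulative totals, usable as worked-example inputs to icer()
reported:
  reference:
    total_cost: 269164.88
    qalys: 2.190
  comparator:
    total_cost: 282340.19
    qalys: 2.254
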