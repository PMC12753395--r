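# Synthetic demonstration configuration: generator-driven values only,
# with directly specified per-cycle costs (no calibration targets).
n_cycles: 60
wtp: 150000
discount: 0.03
half_cycle: true
reference:
  label: armA
  median_dfs: 10
  median_os: 18
  u_dfs: 0.75
  u_pd: 0.60
  initial_cost: 60000
  cycle_cost_alive: 2500
comparator:
  label: armB
  median_dfs: 12
  median_os: 21
  u_dfs: 0.78
  u_pd: 0.60
  initial_cost: 68000
  cycle_cost_alive: 2500
sensitivity:
  fraction: 0.20
  n_draws: 200
  seed: 42
  distributions: uniform
cohort:
  n_per_arm: 150
  cost_cv: 0.25
  accrual_window: 24
  followup_cutoff: 60
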