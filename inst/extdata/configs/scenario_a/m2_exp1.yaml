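name: scenario_a_m2_exp1
scenario: a
params:
  m: 2
  L: 1.0
  A_max: 10.0
  demand_mean: 4.0
  demand_cv: 0.5
  D_max: 100.0
  C_h: 1.0
  C_v: 3.0
  C_s: 5.0
  C_w: 7.0
  gamma: 0.99
  issuing: lifo
vi:
  tolerance: 0.0001
search:
  sampler: grid
  rollouts_per_candidate: 4000.0
rollout:
  n_rollouts: 10000.0
  horizon_days: 365.0
  warmup_days: 100.0
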