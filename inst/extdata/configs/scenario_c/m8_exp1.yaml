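name: scenario_c_m8_exp1
scenario: c
params:
  m: 8.0
  A_max: 20.0
  D_max: 20.0
  life_on_arrival: exogenous
  C_h: 1.0
  C_s: 20.0
  C_w: 5.0
  C_f: 10.0
  gamma: 0.95
vi:
  tolerance: 0.0001
search:
  sampler: nsga2
  population: 50.0
  rollouts_per_candidate: 4000.0
rollout:
  n_rollouts: 10000.0
  horizon_days: 365.0
  warmup_days: 100.0
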