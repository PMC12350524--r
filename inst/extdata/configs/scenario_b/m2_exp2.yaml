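name: scenario_b_m2_exp2
scenario: b
params:
  m: 2.0
  mu_a: 7.0
  mu_b: 3.0
  rho: 0.5
  A_max_a: 14.0
  A_max_b: 6.0
  C_r_a: 1.0
  C_r_b: 1.0
  C_v_a: 0.5
  C_v_b: 0.5
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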