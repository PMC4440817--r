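landscape:
  seed: 1959.0
  min_area_ha: 100.0
  generator:
    nx: 40.0
    ny: 30.0
    cell_size_ha: 25.0
economics:
  annual_price_growth: 0.02
  years_per_step: 5.0
behaviour:
  initial_likelihood: 0.2
  dairy_penalty: 0.75
  forest_lock_steps: 5.0
  k_social: 10.0
  network_effects: yes
demography:
  succession_rate: 0.75
  steps_per_stage: 1.0
scenario:
  ghg_price: 0.0
  n_steps: 10.0
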