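# Example cowspace configuration. Every field shown here equals the package
# default; omit any field (or block) to keep the default.

milk_model:
  primiparous: {a: 31.0, b: -12.0, k: 0.045, c: -0.022}
  multiparous: {a: 41.0, b: -16.0, k: 0.055, c: -0.040}
  scenario_effect: 1.1          # L/day added in the high-space scenario
  gestation_effects: [-0.8, -3.0, -5.5, -8.0, -11.0]  # L/day per stage
  sd: {a: 2.5, b: 2.0, k: 0.005, c: 0.005}            # per-cow draw sds
  gestation_breaks: [1, 57, 113, 169, 225]            # days pregnant
  max_gestation: 285

reproduction:
  conception:                   # [mean, sd] days from calving to conception
    control_primiparous: [82, 10]
    high_primiparous: [155, 25]
    control_multiparous: [108, 15]
    high_multiparous: [133, 25]
  gestation_bounds: [275, 285]  # uniform, days
  dry_bounds: [42, 60]          # uniform, days
  exit_bounds: [1, 305]         # uniform, final-lactation exit DIM
  conception_floor: 21          # redraw conception draws below this
  n_exit_draws: 5

economics:
  margin_bounds: [0.17, 0.23]               # GBP per liter over purchased feed
  primiparous_cost_bounds: [32.43, 129.72]  # GBP per calving event
  multiparous_cost_bounds: [49.54, 198.16]  # GBP per calving event
  days_per_year: 365.25
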