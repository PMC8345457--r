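horizon_days: 1000
days_per_month: 30
start_month: 12
iterations: 50
base_seed: 1
summary_mode: mean_ci95
rate_conversion: uniform
exposure_mode: worst_case
species:
  rabbit:
    thresholds:
    - 0
    - 30
    - 120
    - 270
    mortality:
    - 0.77
    - 0.38
    - 0.11
    - 0.11
    reproduction:
    - 0.0
    - 0.0
    - 0.0
    - 4.0
    season:
    - 12
    - 1
    - 2
    - 3
    - 4
    - 5
nests:
- nest_id: nest1
  species: rabbit
  location:
  - 0.0
  - 0.0
  initial_counts:
  - 0
  - 0
  - 60
  - 80
  sex_ratio_male: 0.5
  feeding_radius: 150.0
landscape:
  fields: []
applications: []
residue_parameters: []
intake: ~
toxicity_profiles: []
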