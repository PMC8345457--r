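horizon_days: 540
days_per_month: 30
start_month: 12
iterations: 50
base_seed: 1
summary_mode: mean_ci95
rate_conversion: uniform
exposure_mode: landscape
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
  - 200.0
  - 200.0
  initial_counts:
  - 0
  - 0
  - 60
  - 80
  sex_ratio_male: 0.5
  feeding_radius: 100.0
- nest_id: nest2
  species: rabbit
  location:
  - 2200.0
  - 200.0
  initial_counts:
  - 0
  - 0
  - 60
  - 80
  sex_ratio_male: 0.5
  feeding_radius: 100.0
- nest_id: nest3
  species: rabbit
  location:
  - 4200.0
  - 200.0
  initial_counts:
  - 0
  - 0
  - 60
  - 80
  sex_ratio_male: 0.5
  feeding_radius: 100.0
- nest_id: nest4
  species: rabbit
  location:
  - 6200.0
  - 200.0
  initial_counts:
  - 0
  - 0
  - 60
  - 80
  sex_ratio_male: 0.5
  feeding_radius: 100.0
landscape:
  fields:
  - field_id: f1
    inner_band_width: 0.0
    outer_band_width: 0.0
    rect:
    - 0.0
    - 0.0
    - 400.0
    - 400.0
    crop_schedule:
    - crop: cereal
      start_day: 0.0
      end_day: 100000.0
  - field_id: f2
    inner_band_width: 0.0
    outer_band_width: 0.0
    rect:
    - 2000.0
    - 0.0
    - 2400.0
    - 400.0
    crop_schedule:
    - crop: cereal
      start_day: 0.0
      end_day: 100000.0
  - field_id: f3
    inner_band_width: 0.0
    outer_band_width: 0.0
    rect:
    - 4000.0
    - 0.0
    - 4400.0
    - 400.0
    crop_schedule:
    - crop: cereal
      start_day: 0.0
      end_day: 100000.0
  - field_id: f4
    inner_band_width: 0.0
    outer_band_width: 0.0
    rect:
    - 6000.0
    - 0.0
    - 6400.0
    - 400.0
    crop_schedule:
    - crop: cereal
      start_day: 0.0
      end_day: 100000.0
applications:
- pesticide: bromoxynil
  field_id: f2
  day: 15
  rate: 0.05
  drift_fractions:
    core: 1.0
    inner: 1.0
    outer: 0.0
    background: 0.0
- pesticide: bromoxynil
  field_id: f3
  day: 15
  rate: 0.1
  drift_fractions:
    core: 1.0
    inner: 1.0
    outer: 0.0
    background: 0.0
- pesticide: bromoxynil
  field_id: f4
  day: 15
  rate: 0.2
  drift_fractions:
    core: 1.0
    inner: 1.0
    outer: 0.0
    background: 0.0
residue_parameters:
- pesticide: glyphosate
  food_item: cereal
  rud: 85.0
  dt50: 10.0
- pesticide: bromoxynil
  food_item: cereal
  rud: 85.0
  dt50: 3.0
intake:
  species: rabbit
  fir_over_bw: 0.45
toxicity_profiles:
- pesticide: bromoxynil
  acute:
    slope: 0.03125
    intercept: -0.3125
  chronic:
    slope: 0.0730994
    intercept: 0.0
    window: 5
  reproduction:
    slope: 0.1
    intercept: 0.0
    window: 5
  mortality_lag_months: 1
  reproduction_lag_months:
  - 1
  - 2
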