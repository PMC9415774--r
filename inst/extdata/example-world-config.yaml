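preset: default
n_districts: 20
n_coastal: 6
extent: 100.0
coastal_band: 0.2
layers_interior:
- 2
- 4
layers_coastal:
- 3
- 6
frac_nonag_interior: 0.4
frac_nonag_coastal: 0.6
wage_meanlog: 4.605170185988092
wage_sdlog: 0.5
nonag_premium: 1.3
coastal_premium: 1.25
capacity_mean: 10.0
access_wage_multiple: 2.0
access_sdlog: 0.4
access_nonag_factor: 1.4
time_req_values:
- 0.25
- 0.333333333333333
- 0.5
- 1.0
time_req_probs:
- 0.2
- 0.3
- 0.35
- 0.15
amenity: no
amenity_value: 20.0
base_depth_coastal_meanlog: -0.510825623765991
base_depth_coastal_sdlog: 0.4
base_depth_interior_max: 0.1
sens_coastal:
- 0.8
- 1.6
sens_interior:
- 0.0
- 0.15
credit_multiplier: 1.0
moving_cost_base: 150.0
moving_cost_per_dist: 1.5
debt_interest_rate: 0.05
informal_income: 75.0
consumption_need: 60.0
consumption_mpc: 0.5
consumption_wealth_rate: 0.05
endowment_fraction: 0.3
income_floor: 0.01
wealth_meanlog: 5.703782474656201
wealth_sdlog: 0.7
rho_range:
- 0.3
- 1.8
discount_range:
- 0.05
- 0.15
p_reconsider_mean: 0.1
p_reconsider_rel_range:
- 0.5
- 1.5
p_meet_range:
- 0.02
- 0.08
p_interact_range:
- 0.1
- 0.3
init_links_mean: 1.5
init_links_local_frac: 0.7
guarantee_placement: no
schedules:
  fertility:
    age_lo:
    - 0.0
    - 15.0
    - 20.0
    - 30.0
    - 40.0
    - 50.0
    rate:
    - 0.0
    - 0.05
    - 0.08
    - 0.04
    - 0.01
    - 0.0
  mortality:
    age_lo:
    - 0.0
    - 1.0
    - 5.0
    - 15.0
    - 40.0
    - 60.0
    - 70.0
    - 80.0
    rate:
    - 0.04
    - 0.005
    - 0.001
    - 0.002
    - 0.005
    - 0.02
    - 0.06
    - 0.15
  adult_age: 15.0
network:
  decay: 0.08
  alpha: 0.25
  w0: 0.5
  w_min: 0.05
  phi: 0.2
  info_share_prob: 0.5
  distance_penalty: 1.0
  meet_weights:
    same_district: 3.0
    fof: 2.0
    same_sector: 2.0
    other: 1.0
decision:
  k_locations: 4
  lambda: 2.25
  horizon_quarters: 20
  max_layers: 3
damage:
  delta_ag: 0.5
  delta_nonag: 0.2
  recovery_quarters: 4
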