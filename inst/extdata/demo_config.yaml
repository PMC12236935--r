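# Demonstration pipeline configuration: a 25-tract synthetic study area
# around a medical-waste-incinerator-like point source, 240 hours of
# synthetic meteorology, and the four throughput x control scenarios.
seed: 42
study_area:
  n_tracts: 25
  domain_radius: 50000
meteorology:
  n_hours: 240
  prevailing_direction: 290
grid:
  n_directions: 36
  n_rings: 40
  radius: 50000
  flagpole_height: 2
urban_population: 565000
fixtures:
  emission_factors: emission_factors_synthetic.csv
  control_efficiencies: control_efficiencies_synthetic.csv
  concentration_response: crf_synthetic.csv
  baseline_rates: baseline_rates_synthetic.csv
  unit_values: unit_values_synthetic.csv
  deflator: cpi_deflator.csv
facilities:
  medwaste:
    stack: {height: 30, diameter: 1.2, exit_velocity: 15, exit_temperature: 450}
scenarios:
  - label: typical_controlled
    sources: [{facility: medwaste, throughput: 26000, condition: controlled}]
  - label: typical_uncontrolled
    sources: [{facility: medwaste, throughput: 26000, condition: uncontrolled}]
  - label: max_controlled
    sources: [{facility: medwaste, throughput: 56000, condition: controlled}]
  - label: max_uncontrolled
    sources: [{facility: medwaste, throughput: 56000, condition: uncontrolled}]
savings:
  - {label: typical_controls, from: typical_uncontrolled, minus: typical_controlled}
  - {label: max_controls, from: max_uncontrolled, minus: max_controlled}
disparities:
  scenarios: [typical_controlled, typical_uncontrolled]
covariates:
  noise_sd: 0
  planted: {}
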