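{
  "seed": 42,
  "landscape": {
    "n_highway_points": 80,
    "n_transect_points": 50,
    "highway_length_km": 20,
    "n_transects": 4
  },
  "groups": {
    "deer": {
      "family": "poisson",
      "count_coefficients": {"intercept": 0.4, "water_500": 0.5},
      "permeability_truth": 0.3,
      "intensity_per_km": 2
    },
    "carnivores": {
      "family": "zip",
      "count_coefficients": {"intercept": 0.8, "gravel_road_len_500": 0.3},
      "zero_coefficients": {"intercept": 0},
      "permeability_truth": 0.106,
      "intensity_per_km": 0.8
    }
  },
  "approaches": ["200m"],
  "mapping": {"approach_buffer_m": 200}
}
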