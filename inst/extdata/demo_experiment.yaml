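# Demo drought experiment: 3 irrigation treatments x 3 plants x 4 days.
# Treatments restore 100% (CTRL), 60% and 30% of soil available water
# capacity; psi trajectories (MPa) span the measured -0.4 .. -1.1 range.
experiment:
  treatments:
    CTRL:  [-0.40, -0.40, -0.40, -0.40]
    IRR60: [-0.40, -0.50, -0.62, -0.75]
    IRR30: [-0.40, -0.62, -0.85, -1.10]
  days: [0, 3, 10, 14]
  n_plants: 3
synthetic:
  n_leaves: 6
  stem_height: 300
  petiole_length: 40
  blade_radius: 35
  position_noise_sd: 0.7
  n_clutter_dark: 150
  n_clutter_blue: 150
  link:
    slope_deg_per_MPa: -50
    intercept_deg: 55
    noise_sd_deg: 2
indices:
  image_size: 192
model:
  n_pairs: 500
  slope: 3.3027
  intercept: -283.42
  psa_range: [400, 1000]
  noise_sd: 20
  k: 10
seed: 1
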