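# Reduced-scale working preset: four ~256-point sample sets, 5 split
# ratios, 10 seeded splits, two shallow model families.  Completes on one
# CPU in minutes; intended for desk testing of the full pipeline.
name: desk
seed: 1
space:
  names: [sigma_C, sigma_H, eps_C, eps_H]
  lower: [0.0500, 0.0450, 0.1500, 0.0100]
  upper: [0.3500, 0.3500, 1.1500, 0.1500]
sampling:
  datasets:
    - name: GridA
      strategy: grid
      min:  [0.0750, 0.0683, 0.2465, 0.0300]
      step: [0.08333333, 0.07583333, 0.27383333, 0.03333333]
      max:  [0.3250, 0.2958, 1.0680, 0.1300]
    - name: GridB
      strategy: grid
      min:  [0.0500, 0.0455, 0.1643, 0.0200]
      step: [0.1000, 0.0910, 0.32860, 0.0400]
      max:  [0.3500, 0.3185, 1.1501, 0.1400]
    - name: SobolA
      strategy: sobol
      m: 8
      lower: [0.0500, 0.0450, 0.1500, 0.0200]
      upper: [0.3500, 0.3200, 1.1500, 0.1400]
    - name: SobolB
      strategy: sobol
      m: 8
      scramble_seed: 20
      lower: [0.0500, 0.0450, 0.1500, 0.0100]
      upper: [0.3500, 0.3500, 1.1500, 0.1500]
oracle:
  target_density: 700
  noise_sd: 5
  rugged_amplitude: 60
  failure_prob: 0.05
preprocess:
  plaus_low: 0
  plaus_high: 1500
harness:
  ratios: {start: 0.55, stop: 0.95, step: 0.10}
  seeds_per_ratio: 10
  families:
    - {family: random_forest, ntree: [100]}
    - {family: fnn, hidden: 16}
selection:
  k: 3
conformers:
  n_conformers: 25
optimizer:
  init: [0.3400, 0.2500, 0.4500, 0.0900]
  w_dens: 1
  w_rce: 1
  tol: 1.0e-6
  max_iter: 1000
  n_starts: 3
verify:
  n_rep: 3
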