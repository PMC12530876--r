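# Full-scale preset: the four canonical sample sets (two grids of 1296 and
# 2401 points, two 2048-point Sobol sequences over slightly different
# boxes), 19 split ratios with 50 seeded splits each, and the complete
# hyperparameter grids of all five model families.  Provided for plan
# bookkeeping and full-scale reruns; the reduced `desk` preset is the
# working default.
name: paper
seed: 1
space:
  names: [sigma_C, sigma_H, eps_C, eps_H]
  lower: [0.0500, 0.0450, 0.1500, 0.0100]
  upper: [0.3500, 0.3500, 1.1500, 0.1500]
sampling:
  datasets:
    - name: Grid1296
      strategy: grid
      min:  [0.0750, 0.0683, 0.2465, 0.0300]
      step: [0.0500, 0.0455, 0.1643, 0.0200]
      max:  [0.3250, 0.2958, 1.0680, 0.1300]
    - name: Grid2401
      strategy: grid
      min:  [0.0500, 0.0455, 0.1643, 0.0200]
      step: [0.0500, 0.0455, 0.1643, 0.0200]
      max:  [0.3500, 0.3185, 1.1501, 0.1400]
    - name: Sobol1
      strategy: sobol
      m: 11
      lower: [0.0500, 0.0450, 0.1500, 0.0200]
      upper: [0.3500, 0.3200, 1.1500, 0.1400]
    - name: Sobol2
      strategy: sobol
      m: 11
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
  ratios: {start: 0.05, stop: 0.95, step: 0.05}
  seeds_per_ratio: 50
  families:
    - {family: linear}
    - {family: polynomial, degree: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]}
    - {family: random_forest, ntree: [10, 100, 250, 500, 750, 1000]}
    - {family: gaussian_process, kernel: [rbf, matern, rq]}
    - {family: fnn}
selection:
  k: 12
conformers:
  n_conformers: 97
optimizer:
  init: [0.3400, 0.2500, 0.4500, 0.0900]
  w_dens: 1
  w_rce: 1
  tol: 1.0e-6
  max_iter: 1000
  n_starts: 5
verify:
  n_rep: 3
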