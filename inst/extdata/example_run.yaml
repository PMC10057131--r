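# Example run configuration for the chiralpmf command-line driver.
seed: 1
output_dir: run
segments:
  - {start: -4.0, stop: -1.5, step: 0.1, include_start: true, include_stop: false}
  - {start: -1.5, stop: 1.5, step: 0.05, include_start: true, include_stop: true}
  - {start: 1.5, stop: 3.0, step: 0.1, include_start: false, include_stop: true}
force_constant: 500
n_equil_samples: 2000
n_prod_samples: 4000
sample_interval: 5
surface:
  reactant_rc: -3.0
  ts_rc: -0.5
  barrier: 17.0
  product_rc: 2.0
  overall_dG: -7.0
langevin: {dt: 0.01, friction: 1000, temperature: 300}
wham: {bin_width: 0.02, tolerance: 1.0e-7, max_iterations: 100000, convention: half_k}
bootstrap: {n_boot: 20}
ts_search: [-2, 1]
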