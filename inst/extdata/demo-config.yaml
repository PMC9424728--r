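# Demo pipeline configuration: default genome and pools, lighter scan.
seed: 1
simulation:
  n_f2: 150
  pool_size: 15
  coverage_g: 95
  coverage_y: 75
  error_rate: 0.01
scan:
  span: 0.1
  window_bp: 1000000
  step_bp: 100000
  quantile: 0.99
  min_depth: 10
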