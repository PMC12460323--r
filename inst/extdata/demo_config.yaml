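# Synthetic demonstration of the full workflow: a 48-unit lattice panel
# over 30 years with nonstationary coefficient surfaces, analysed by all
# four stages (Moran's I series, Gi* windows + persistence, factor /
# interaction / sensitivity detection, spatiotemporal weighted
# regression).
simulate:
  nrows: 6
  ncols: 8
  years: 30
  noise_sd: 0.5
  seed: 2024
bin_width: 5
moran:
  significance_z: 2.58
  assumption: randomization
gistar:
  row_standardized: false
geodetector:
  alpha: 0.05
  class_range: [3, 4, 5, 6]
  sensitivity:
    perturb_fraction: 0.10
    n_replicates: 10
    seed: 7
gtnnwr:
  enabled: true
  seed: 48
  hyperparams:
    epochs: 400
    swnn_hidden: [64, 32]
    val_interval: 25
    log_interval: 200
seed: 1
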