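# Demonstration pipeline configuration for the command-line front end:
#   Rscript inst/cli/onsetrisk.R all --config inst/extdata/demo_config.yaml
generator:
  n_individuals: 2000
  n_conditions: 6
  n_latent: 3
  cluster_strength: 1.0
  seed: 7
arch:
  groups: [demog, bb, bbc, blood]
  n_conditions: 6
  k: 16
train:
  epochs: 15
  lr: 0.002
  batch_size: 512
cindex_threshold: 0.6
edge_threshold: 0.3
alpha: 0.05
horizon_months: 120
min_uncensored: 50
out_dir: demo_run
seed: 7
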