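# Reduced-size demonstration configuration: two small simulated cohorts,
# a narrow 4-layer dense network, and shortened permutation counts so the
# full pipeline completes in seconds.
cohort:
  n_samples: 80
  n_genes: 300
  n_y_linked: 5
  n_xist_like: 5
  n_xci_escape: 5
n_cohorts: 2
net:
  total_layers: 4
  hidden_width: 8
  epochs: 25
  batch_size: 16
ig_steps: 16
top_k: 30
min_sets: 2
n_perm: 200
n_lasso_features: 20
n_folds: 5
n_targets: 4
n_decoys: 6
utr_length: 300
seed: 1
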