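seed: 1
data:
  simulate:
    n_compartments: 3
    cells_per_compartment: 500
    n_genes: 2000
    n_signature_per_compartment: 30
    effect_logfc: 1.5
    nb_dispersion: 0.5
    n_datasets: 2
    batch_logfc_sd: 0.3
training_datasets: [ds1]
validation_datasets: [ds2]
preprocess:
  qc: true
  min_genes: 200
  max_genes: 4000
  max_mito_frac: 0.2
features:
  method: hvg
  n_top: 100
  cell_type: resident_mac
model:
  hidden_sizes: [128, 64]
  dropout: 0.2
  learning_rate: 0.001
  max_epochs: 200
  early_stop_patience: 10
  batch_size: 64
  attention: true
apply:
  group_by: [dataset]
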