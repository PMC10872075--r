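# Example drpfuse run configuration (paths relative to the working dir).
# Run:  drpfuse simulate --config example_run.yaml
#       drpfuse train    --config example_run.yaml
seed: 1
scheme: cell_line
k_folds: 5
output_dir: drpfuse_out
synthetic:
  n_cell_lines: 60
  n_lineages: 4
  features_per_omic: {EXP: 30, CNV: 20}
  n_drugs: 20
  beta: 0.3
  noise_sd: 0.05
paths:
  omics:
    EXP: drpfuse_out/data/omic_EXP.csv
    CNV: drpfuse_out/data/omic_CNV.csv
  drug_catalog: drpfuse_out/data/drug_catalog.csv
  responses: drpfuse_out/data/responses.csv
model:
  preset: refined
  omic_types: [EXP, CNV]
  d_omic_latent: 8
  d_drug_latent: 16
  epochs: 60
lds:
  n_bins: 100
  kernel: gaussian
evaluate:
  window: 200
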