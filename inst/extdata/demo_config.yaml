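# Demo pipeline configuration: a small synthetic young-age cohort with planted
# age CpGs, desk-scale network widths and epoch budgets.
seed: 7
simulate:
  n_samples: 150
  n_probes: 400
  n_informative: 40
  age_range: [10.0, 30.0]
  noise_sd: 0.3
  missing_rate: 0.01
  sex_block: true
filter:
  keep_sex_chromosomes: false
impute:
  k: 10
split:
  ratio: 0.8
autoencoder:
  hidden_widths: [32, 16, 8]
  max_epochs: 50
  batch_size: 64
  learning_rate: 0.001
regressor:
  hidden_widths: [32, 32, 32]
  max_epochs: 300
  batch_size: 64
classifiers:
  cutoffs: [18, 21]
  max_epochs: 120
benchmark:
  enabled: false
lightup:
  top_n: 80
  mode: most_negative
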