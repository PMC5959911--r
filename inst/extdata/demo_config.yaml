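# Demo pipeline configuration: every stage on synthetic data, small enough
# to run end-to-end in seconds. See ?run_pipeline for the key reference.
seed: 1
screen:
  n_perturbations: 200
  fraction_sensitiser: 0.2
  fraction_toxic: 0.05
  fraction_both: 0.05
  noise_cv: 0.05
  n_replicates: 2
  sens_threshold: 80
  vehicle_threshold: 80
  drug: docetaxel
growth:
  doubling_time_h: 24
  t_end_h: 48
  step_h: 2
  start_confluency: 1
dose_response:
  ic50: 5
  hill: 1
  lower: 5
  upper: 100
  doses: [0.25, 0.5, 1, 2, 4, 8, 16, 32, 64]
  n_replicates: 4
  noise_cv: 0.05
expression:
  n_genes: 300
  n_planted_down: 30
  alpha: 0.05
  mirna: miR-sim
enrichment:
  n_sets: 10
  set_size: 25
  universe_size: 300
  top: 10
tumor:
  n_genes: 300
  n_normal: 12
  n_tumor: 12
  n_planted_up: 20
  fold: 2
  missing_rate: 0.05
  alpha: 0.05
  min_fold: 1.5
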