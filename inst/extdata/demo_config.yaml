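# Small end-to-end demonstration run (about a minute on one CPU).
# Usage from R:
#   run_pipeline(system.file("extdata", "demo_config.yaml",
#                            package = "painrhythm"))
seed: 2019
out_dir: painrhythm_demo
stages:
  simulate: true
  phenotype: true
  cohort_stats: true
  preprocess: true
  de: true
  network: true
  replication: true
cohort:
  low_noise: true
counts:
  n_transcripts: 600
  planted_module_size: 40
  module_effect: 1.2
replication:
  n_users: 15
  n_nonusers: 15
  n_genes: 300
  set_size: 25
  n_decoy_sets: 5
network:
  min_size: 12
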