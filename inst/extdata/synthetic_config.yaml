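# Example pipeline configuration: a small synthetic two-core study.
# Run with:  run_pipeline(system.file("extdata", "synthetic_config.yaml",
#                                     package = "nitribalance"), out_dir = "out")
synthetic:
  n_cores: 2
  depths_cm: [5, 15, 25, 35, 45]
  opd_cm: 30
  r_true: 10
  f_candidate: 0.65
  background_otus: 10
  read_depth: 5000
  qpcr_sigma: 0.3
seed: 1
band: literature
ci_level: 0.99
n_boot: 2000
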