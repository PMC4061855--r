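# Example pipeline configuration: a scaled-down synthetic oddball study.
# Run with: Rscript inst/scripts/run_pipeline.R inst/extdata/example_config.yaml
design:
  groups: {English: 3, Chinese: 3}
  standards_per_block: 18
  deviants_per_block: 2
  artifact_rate: 0.1
  seed: 7
wavelet: {f_min: 8, f_max: 50, f_step: 1, m: 9, fs: 512}
taper_fraction: 0.1
baseline: [-280, -100]
schemes: [midline, lateral]
ptp_threshold: 150
min_trials: 2
bands:
  alpha: {reference: Cz}
  gamma: {reference: FCz}
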