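# Example pipeline configuration for the manopull CLI.
# Values omitted here fall back to the package defaults
# (12 + 26 patients, 1 cm/s pull at 10 samples/s, noise sd 8 mmHg,
#  cut-off 75 mmHg & 0.7 on the per-patient mean).
simulation:
  n_group_a: 12
  n_group_b: 26
  noise_sd: 8
  seed: 42
analysis:
  smoothing_window: 3
  max_maneuvers: 6
rule:
  anterior_threshold: 75
  ratio_threshold: 0.7
  combination: AND
  aggregate: mean
output:
  figures: true
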