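# Example run configuration for visearch::read_config().
# Fields present here override the package defaults; everything else
# keeps its default_config() value.
seed: 42
simulate:
  n_per_group: [8, 8, 8, 8]
  render_samples: false
  sampling_rate: 120
detector:
  min_duration_ms: 60
  max_dispersion_deg: 2
  dispersion_metric: sum
  gap_bridge_ms: 75
segmentation:
  window_ms: [1700, 3300]
  max_prescan_fixations: 1
  max_prescan_duration_ms: 300
metrics:
  min_trials: 10
rqa:
  min_line_length: 2
multimatch:
  amp_threshold: 0.1
  dir_threshold_deg: 45
  dur_threshold_ms: 300
  aggregate: median
stats:
  outlier_rule: []
  k_sd: 3
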