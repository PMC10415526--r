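# Example swnet pipeline configuration.
# Defaults are the reference analysis conditions; list only deviations.
version: 1
seed: 7
simulate:
  enabled: true
  n_low: 16
  n_high: 13
  duration_s: 420   # seconds of ROI-level signal per subject
  rate_hz: 250      # ROI-level sampling rate (post-downsampling rate)
connectivity:
  band: [13.0, 30.0]   # beta
  epoch_length_s: 2
graph:
  n_surrogates: 100
  surrogate_mode: degree_preserving   # or weight_shuffle
stats:
  outlier_k: 3     # "extreme outlier" fences, Q1/Q3 +/- k*IQR
  alpha: 0.05
preprocess:
  target_hz: 250
  band: [0.1, 47.0]
  epoch_length_s: 2
  reject_variant: epoch_mean   # or samplewise
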