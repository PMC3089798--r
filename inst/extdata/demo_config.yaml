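# Demo configuration for run_all(): thresholds and scan settings at their
# defaults, with a fixed master seed.
de:
  p1_min: 0.999
  abs_fc_min: 1.4
dre:
  core: GCGTG
  flank_bp: 7
  distance_threshold: 3.0
  ms_min: 0
chx:
  retention_alpha: 0.5
  times_hr: [4, 12]
eb:
  prior_df: 4
  pi1: 0.01
  effect_var_scale: 25
seed: 17
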