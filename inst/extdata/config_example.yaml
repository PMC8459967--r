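# Every pipeline parameter at its default; see ?default_config.
selection:
  min_segment_len: 6
  shared_window: 6
  gravy_threshold: 0.0
  max_run: 3
  preferred_min_len: 9
  max_len: 20
  consensus_gap_rule: majority
  uniqueness_scope: cross_grain
  gravy_on_ambiguity: error
serology:
  titer_target_od: 1.0
  titer_mode: interpolated
  cutoff_confidence: 0.999
  retention_titer: 4000
  retention_rule: strict_greater
seed: 1
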