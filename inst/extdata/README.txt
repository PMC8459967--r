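gpt_abundance_synthetic.tsv
  Illustrative, synthetic gluten-proportion mapping for the default
  synthetic grain set (grain, gpt, abundance as a fraction of the grain's
  gluten). These numbers are placeholders for a real per-GPT gluten
  composition table and exist so the ranking stage can be exercised; they
  are NOT measured values.

config_example.yaml
  A complete configuration file with every tunable parameter spelled out at
  its default; see ?default_config for meanings and units.
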