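# Sample configuration: temporal dialect options, named-day lexicon,
# rendering and mining parameters.
temporal:
  pivot: 30
  lexicon:
    "korean thanksgiving day": "2002-09-21"
render:
  unit_spacing: 170
  wing_angle: 45
  problem_color: "#CC0000"
  action_color: "#0033CC"
mine:
  min_support_target: 0.8
  max_len: 2
  mode: semantic_type
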