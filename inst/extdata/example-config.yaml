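# Example somnus configuration: overrides merge over snn_config() defaults.
# Unknown groups or fields are rejected at load time.
synapse:
  gamma: 0.6
homeostasis:
  target_rate: 1
env:
  density: 0.10
schedule:
  preset: desk
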