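# Example configuration overriding a handful of defaults; unknown keys are
# rejected by load_config(). All other parameters keep their package defaults.
network:
  n_E: 100
  n_I: 20
  A_lat: 5.0
protocol:
  stim_duration: 300
  blank_duration: 50
  n_train: 50000
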