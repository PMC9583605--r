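# desk preset: reduced panel for ensemble property checks
mesh:
  dy: 0.005
  width: 0.1
  depth: 0.6
scenario:
  heterogeneity: EXTR
  precipitation: HRE
  n_realizations: 5
  seed: 1
  t_end: 60
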