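# full preset: study geometry and span
mesh:
  dy: 0.005
  width: 0.3
  depth: 2.0
scenario:
  heterogeneity: EXTR
  precipitation: HRE
  n_realizations: 100
  seed: 1
  t_end: 365
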