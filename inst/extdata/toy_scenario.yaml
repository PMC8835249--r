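# two-isoform toy scenario used in examples and tests
isoforms:
  a: 80
  b: 68
antibodies:
  ab-a:
    target: a
    affinity: 2
    cross_reactivity:
      b: 0.25
  ab-b:
    target: b
    affinity: 3
  ab-tag:
    target: TAG
    affinity: 1.5
    cross_reactivity:
      a: 1
      b: 1
samples:
  S-a:
    abundance: {a: 10, b: 0}
    is_standard: true
    dilution_factor: 10
  S-b:
    abundance: {a: 0, b: 20}
    is_standard: true
    dilution_factor: 20
  U1:
    abundance: {a: 0.4, b: 0.9}
  U2:
    abundance: {a: 1.2, b: 0.1}
n_blots: 2
gain_log_sd: 0.1
noise_cv: 0.05
background: 0
seed: 42
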