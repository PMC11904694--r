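# Demo workflow configuration: generate the benchmark synthetic study and
# evaluate all three candidate mechanisms on it.
synth: true
models:
  - borderline
  - sn1
  - sn2
objective: wls
seed: 1
outDir: kinwfi-out
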