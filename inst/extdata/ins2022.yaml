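# The shipped four-component INS configuration.
name: INS-2022
components:
  - index: LCR
    threshold: 2813
    direction: below
  - index: CAR
    threshold: 0.165
    direction: at_or_above
  - index: ALI
    threshold: 33
    direction: below
  - index: NRI
    threshold: 94
    direction: below
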