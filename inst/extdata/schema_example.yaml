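# Example column-mapping schema: the source file calls albumin "ALB" and
# reports it in g/dL; every other column already uses canonical names/units.
columns:
  albumin: ALB
units:
  albumin: g/dL
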