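# Default analysis weight table: consequence class (and, for missense, the
# number of concordant in-silico damaging predictions) -> collapsing weight.
name: functional
classes:
  pLoF: 1.0
  inframe_indel: 0.8
  missense:
    - {min_predictions: 2, weight: 0.8}
    - {min_predictions: 1, weight: 0.5}
    - {min_predictions: 0, weight: 0.2}
  synonymous: 0.0
  other: 0.0
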