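# Empirical-null calibration table: only synonymous variants qualify, so a
# run under this table should carry no true case-control signal.
name: synonymous_calibration
classes:
  pLoF: 0.0
  inframe_indel: 0.0
  missense: 0.0
  synonymous: 1.0
  other: 0.0
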