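# data.table non-standard-evaluation column names used across the package.
utils::globalVariables(c(
  ".", ".N", ".SD", "variant_id", "sample_id", "gene", "weight", "cohort_ac",
  "i.cohort_ac", "canonical", "pos", "damaging_prediction_count",
  "gnomad_popmax_af", "consequence", "transcript", ".canon_rank", ".sev_rank",
  "n", "p", "p_adjust", "p_combined", "q_value", "observed_p", "status"
))
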