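exclusions:
  - rsid: rs8042680
    reason: hwe_failure
    note: PRC1 locus; deviation from Hardy-Weinberg equilibrium (Bonferroni-corrected P < 0.05)
  - rsid: rs1470579
    reason: hwe_failure
    note: IGF2BP2 locus; deviation from Hardy-Weinberg equilibrium (Bonferroni-corrected P < 0.05)
  - rsid: rs11642841
    reason: bmi_primary_effect
    note: FTO locus; excluded because its primary effect is on body mass index
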