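exclusions:
  - rsid: rs10885122
    reason: hwe_failure
    note: ADRA2A locus; deviation from Hardy-Weinberg equilibrium (Bonferroni-corrected P < 0.05)
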