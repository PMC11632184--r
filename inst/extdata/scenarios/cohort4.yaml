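# admixed mixture: 50/25 from the African-analog group, 15/10 from the
# admixed-American-analog group (75% AFR, 25% AMR)
proportions:
  AFR1: 0.50
  AFR2: 0.25
  AMR2: 0.15
  AMR1: 0.10
n_subjects: 2000
seed: 1
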