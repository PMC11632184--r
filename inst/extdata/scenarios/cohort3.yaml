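# equal thirds across an East-Asian-, European- and admixed-American-analog
# population (33.3% per super group)
proportions:
  ASN1: 0.3334
  EUR1: 0.3333
  AMR1: 0.3333
n_subjects: 2000
seed: 1
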