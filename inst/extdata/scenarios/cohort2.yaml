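# 25% each from the four East-Asian-analog populations (100% ASN group)
proportions:
  ASN1: 0.25
  ASN2: 0.25
  ASN3: 0.25
  ASN4: 0.25
n_subjects: 2000
seed: 1
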