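# 25% each from the four European-analog populations (100% EUR group)
proportions:
  EUR1: 0.25
  EUR2: 0.25
  EUR3: 0.25
  EUR4: 0.25
n_subjects: 2000
seed: 1
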