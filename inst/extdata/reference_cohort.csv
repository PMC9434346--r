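name,count
outcome_type0,66
outcome_type1,47
outcome_type2,29
scans_baseline,186
scans_month1,186
scans_month3,157
scans_month12,142
train_baseline,148
train_month1,148
train_month3,119
train_month12,104
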