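age_group,class,mean_density,sem
P8,mel_smi_neg,116,9
P8,mel_smi_pos,57,5
P8,smi_only,19,3.3
P8,m1,39,2
P8,m2,74,6
P8,m3,3,1
P8,m1_displaced,13,3
P15,mel_smi_neg,108,4
P15,mel_smi_pos,35,3
P15,smi_only,23,4
P15,m1,39,2
P15,m2,68,2
P15,m3,2.8,0.4
P15,m1_displaced,11,2
P30,mel_smi_neg,106,6
P30,mel_smi_pos,23,2
P30,smi_only,31,3.5
P30,m1,36,2
P30,m2,67,6
P30,m3,3,1
P30,m1_displaced,10,2
P150,mel_smi_neg,54,2
P150,mel_smi_pos,1.1,0.3
P150,smi_only,58.9,8
P150,m1,28,2
P150,m2,31,2
P150,m3,1.0,0.3
P150,m1_displaced,8,2
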