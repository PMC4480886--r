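age_group,subtype,r_max,ir_half,hill_n,latency_tau,lat_scale,adapt_tau,recover_tau,off_tau,baseline_rate,shift_gain,kcl_rate,persist_prob,persist_floor
P8,I,17,12.6,0.9,2.0,4,100,35,24,0,0.5,10,0.20,0.004
P8,II,18,13.4,1.0,2.5,4,100,90000,8,0,0.5,4.5,0.00,0.000
P8,III,14,11.0,1.0,1.5,4,25,4500,12,0,0.5,5,0.05,0.003
P15,II,14,13.2,1.0,2.5,4,100,9000,6,0,0.3,2.5,0.30,0.004
P15,III,12,11.0,1.0,2.0,4,140,9000,6,0,0.3,8,0.50,0.100
P30,II,12,13.2,1.0,2.0,5,85,12000,5,0,0.3,2.5,0.25,0.004
P30,III,9,11.0,1.0,2.0,4,120,12000,5,0,0.3,7,0.50,0.100
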