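age_group,subtype,structure,rel_intensity
P8,M1,soma,0.85
P8,M2,soma,0.30
P8,M4,soma,0.75
P8,M1,dendrite,0.50
P8,M2,dendrite,0.40
P8,M4,dendrite,0.40
P15,M1,soma,0.85
P15,M2,soma,0.30
P15,M4,soma,0.52
P15,M1,dendrite,0.45
P15,M2,dendrite,0.20
P15,M4,dendrite,0.05
P30,M1,soma,0.85
P30,M2,soma,0.30
P30,M4,soma,0.52
P30,M1,dendrite,0.42
P30,M2,dendrite,0.20
P30,M4,dendrite,0.05
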