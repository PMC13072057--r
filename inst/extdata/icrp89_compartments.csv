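compartment,volume_fraction,flow_fraction,in_field
aorta,0.010,0.030,TRUE
large_arteries,0.050,0.050,TRUE
large_veins,0.160,0.050,TRUE
superior_vena_cava,0.010,0.015,TRUE
lungs,0.105,0.090,TRUE
brain,0.012,0.120,TRUE
bone,0.070,0.050,TRUE
bronchi,0.003,0.005,TRUE
fat,0.050,0.050,TRUE
lymph_nodes,0.002,0.003,TRUE
skeletal_muscle,0.140,0.170,TRUE
skin,0.030,0.050,TRUE
stomach,0.010,0.010,TRUE
esophagus,0.002,0.003,TRUE
thyroid,0.0006,0.015,TRUE
residual_body,0.3454,0.289,TRUE
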