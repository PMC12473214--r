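trait,pc1,pc2,pc3
height_cm,0.523,0.216,-0.395
branches,0.463,0.543,-0.070
fhr,-0.295,-0.049,-0.450
lsr,0.294,-0.704,0.101
mf_pct,-0.176,0.346,0.705
dry_weight_g,0.556,-0.200,0.360
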