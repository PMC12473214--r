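trait,weight
height_cm,0.210
branches,0.360
fhr,-0.257
lsr,-0.057
mf_pct,0.194
dry_weight_g,0.278
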