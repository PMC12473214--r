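trait,pc1,pc2,pc3
height_cm,0.729,0.247,-0.398
branches,0.645,0.621,-0.071
fhr,-0.412,-0.057,-0.454
lsr,0.410,-0.805,0.102
mf_pct,-0.245,0.395,0.711
dry_weight_g,0.775,-0.229,0.363
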