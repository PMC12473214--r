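trait_a,trait_b,rho
dry_weight_g,height_cm,0.35
dry_weight_g,branches,0.30
dry_weight_g,lsr,0.45
dry_weight_g,fhr,-0.26
height_cm,branches,0.49
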