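component,eigenvalue,variance_pct,cumulative_pct
1,1.946,32.435,32.435
2,1.306,21.771,54.206
3,1.016,16.937,71.143
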