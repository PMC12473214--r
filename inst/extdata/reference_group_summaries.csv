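source,generation,group,trait,n,mean,sd,letter
parent_progeny,P_paternal,none,height_cm,NA,80.85,14.92,
parent_progeny,P_paternal,none,branches,NA,7.31,1.90,
parent_progeny,P_paternal,none,fhr,NA,4.33,0.24,
parent_progeny,P_paternal,none,lsr,NA,1.64,0.35,
parent_progeny,P_paternal,none,mf_pct,NA,0.00,0.00,
parent_progeny,P_paternal,none,dry_weight_g,NA,119.69,29.17,
parent_progeny,P_maternal,none,height_cm,NA,72.48,16.23,
parent_progeny,P_maternal,none,branches,NA,9.16,3.28,
parent_progeny,P_maternal,none,fhr,NA,4.04,0.29,
parent_progeny,P_maternal,none,lsr,NA,1.50,0.29,
parent_progeny,P_maternal,none,mf_pct,NA,68.87,4.29,
parent_progeny,P_maternal,none,dry_weight_g,NA,142.26,43.59,
parent_progeny,F1,all,height_cm,90,75.66,17.64,
parent_progeny,F1,all,branches,90,8.34,3.08,
parent_progeny,F1,all,fhr,90,4.16,0.29,
parent_progeny,F1,all,lsr,90,1.57,0.31,
parent_progeny,F1,all,mf_pct,90,29.03,5.29,
parent_progeny,F1,all,dry_weight_g,90,124.34,47.46,
validation,F1,selected,height_cm,28,86.45,12.04,a
validation,F1,selected,branches,28,11.11,3.02,a
validation,F1,selected,fhr,28,3.99,0.26,b
validation,F1,selected,lsr,28,1.60,0.19,
validation,F1,selected,mf_pct,28,34.68,7.86,c
validation,F1,selected,dry_weight_g,28,161.21,45.34,a
validation,F1,all,height_cm,90,75.66,17.64,c
validation,F1,all,branches,90,8.34,3.08,b
validation,F1,all,fhr,90,4.16,0.29,a
validation,F1,all,lsr,90,1.57,0.31,
validation,F1,all,mf_pct,90,29.03,5.29,c
validation,F1,all,dry_weight_g,90,124.34,19.46,cd
validation,F2,selected,height_cm,45,80.68,9.77,b
validation,F2,selected,branches,45,8.57,1.64,b
validation,F2,selected,fhr,45,3.83,0.30,c
validation,F2,selected,lsr,45,1.62,0.27,
validation,F2,selected,mf_pct,45,50.74,9.92,a
validation,F2,selected,dry_weight_g,45,143.69,44.67,b
validation,F2,unselected,height_cm,45,69.27,11.09,d
validation,F2,unselected,branches,45,7.92,1.81,b
validation,F2,unselected,fhr,45,4.14,0.35,a
validation,F2,unselected,lsr,45,1.59,0.24,
validation,F2,unselected,mf_pct,45,42.71,6.35,b
validation,F2,unselected,dry_weight_g,45,112.80,27.65,d
validation,F2,all,height_cm,90,74.98,11.90,c
validation,F2,all,branches,90,8.24,1.75,b
validation,F2,all,fhr,90,3.97,0.36,b
validation,F2,all,lsr,90,1.61,0.25,
validation,F2,all,mf_pct,90,46.73,8.13,ab
validation,F2,all,dry_weight_g,90,128.24,40.15,c
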