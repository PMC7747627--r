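genotype,trait,control,hnt,printed_pct_diff
Everest,starch_pct,59.80,46.87,-21.62
Jagger X060724,starch_pct,59.27,48.17,-18.73
KS 070736K-1,starch_pct,48.82,51.80,6.12
KS 070729K-26,starch_pct,54.33,44.34,-18.40
KS 070717M-1,starch_pct,56.07,37.20,-33.67
Larry,starch_pct,49.27,45.31,-8.04
P1 X060725,starch_pct,48.36,39.99,-17.32
SY-Monument,starch_pct,63.23,59.40,-6.06
Tascosa,starch_pct,67.77,51.15,-24.52
Tx86A5606,starch_pct,59.66,51.02,-14.47
WB 4458,starch_pct,63.49,59.98,-5.52
WB-Cedar,starch_pct,78.29,64.66,-17.41
Everest,protein_pct,14.92,15.69,5.22
Jagger X060724,protein_pct,14.55,14.57,0.13
KS 070736K-1,protein_pct,14.27,14.73,3.20
KS 070729K-26,protein_pct,13.74,14.42,4.98
KS 070717M-1,protein_pct,15.68,15.56,-0.73
Larry,protein_pct,14.46,14.25,-1.45
P1 X060725,protein_pct,14.36,14.99,4.37
SY-Monument,protein_pct,13.13,14.02,6.80
Tascosa,protein_pct,12.98,13.28,2.34
Tx86A5606,protein_pct,12.64,13.21,4.51
WB 4458,protein_pct,13.36,14.27,6.83
WB-Cedar,protein_pct,14.95,14.92,-0.25
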