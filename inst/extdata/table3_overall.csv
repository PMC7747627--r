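trait,control,hnt,printed_pct_diff,letter_control,letter_hnt
starch_pct,59.03,49.99,-15.31,a,b
protein_pct,14.09,14.49,2.89,a,a
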