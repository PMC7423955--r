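system_label,correction_kcal_mol
apo,-3.1042
gbi1,-3.1030
gbi2,-3.1019
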