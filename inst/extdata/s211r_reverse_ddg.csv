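mutation,tautomer,ddg_calc_kcal_mol,direction
S211R,gbi1,5.9,reversed
S211R,gbi2,1.3,reversed
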