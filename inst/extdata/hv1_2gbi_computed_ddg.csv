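mutation,tautomer,ddg_calc_kcal_mol,err_calc_kcal_mol
D112E,gbi1,4.9,0.7
V178A,gbi1,0.8,0.3
S181A,gbi1,1.1,0.3
V109A,gbi1,0.0,0.3
R208K,gbi1,6.8,0.8
R211S,gbi1,-6.3,0.7
D112E,gbi2,2.3,0.7
V178A,gbi2,0.8,0.3
S181A,gbi2,1.1,0.3
V109A,gbi2,-0.4,0.3
R208K,gbi2,1.7,0.8
R211S,gbi2,-7.1,0.7
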