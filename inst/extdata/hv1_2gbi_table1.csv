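mutation,ddg_expt_kcal_mol,err_expt_kcal_mol,direction
D112E,1.01,0.05,forward
V178A,-0.56,0.05,forward
S181A,0.24,0.05,forward
V109A,-0.26,0.06,forward
R208K,-0.01,0.05,forward
R211S,0.11,0.05,forward
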