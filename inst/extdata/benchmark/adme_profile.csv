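library,fail_lipinski_pct,fail_veber_pct,logbb_neg_pct
Elite libraries,0.0,0.0,65.7
Platinum collection,6.4,7.4,48.0
DIVERSet-CL,0.0,0.1,61.7
DIVERSet-EXP,0.0,0.0,41.7
Drug-like set,0.0,0.2,50.4
Pharmacological diversity set,0.0,0.4,42.4
Maybridge screening collection,2.3,1.5,39.3
Prestwick Chemical Library,7.9,13.5,64.7
MSII full library,0.2,0.8,49.1
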