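library,mean_sim_ecfp2,mean_sim_mdl,mean_sim_phrfc2
Elite libraries,0.229,0.561,0.068
Platinum collection,0.216,0.519,0.098
DIVERSet-CL,0.199,0.515,0.053
DIVERSet-EXP,0.199,0.405,0.074
Drug-like set,0.163,0.415,0.067
Pharmacological diversity set,0.208,0.447,0.084
Maybridge screening collection,0.168,0.355,0.073
Prestwick Chemical Library,0.138,0.346,0.036
MSII full library,0.157,0.107,0.069
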