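library,promiscuous_pct
Elite libraries,1.7
Platinum collection,0.9
DIVERSet-CL,2.7
DIVERSet-EXP,2.5
Drug-like set,2.9
Pharmacological diversity set,1.8
Maybridge screening collection,4.6
Prestwick Chemical Library,11.8
MSII full library,5.0
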