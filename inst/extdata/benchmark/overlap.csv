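library,similar_pct
Elite libraries,0.1
Platinum collection,0.0
DIVERSet-EXP,0.1
Drug-like set,0.1
Pharmacological diversity set,0.0
Maybridge screening collection,0.1
Prestwick Chemical Library,0.0
MSII full library,0.1
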