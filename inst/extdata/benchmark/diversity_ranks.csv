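library,diversity_rank
Elite libraries,7
Platinum collection,8
DIVERSet-CL,7
DIVERSet-EXP,5
Drug-like set,3
Pharmacological diversity set,6
Maybridge screening collection,3
Prestwick Chemical Library,1
MSII full library,2
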