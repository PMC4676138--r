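library,substructure_rank,pharmacophore_rank,fingerprint_rank
Elite libraries,7,6,4
Platinum collection,2,7,1
DIVERSet-CL,7,1,5
DIVERSet-EXP,1,2,2
Drug-like set,3,3,6
Pharmacological diversity set,4,4,7
Maybridge screening collection,5,5,2
Prestwick Chemical Library,7,8,8
MSII full library,6,8,3
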