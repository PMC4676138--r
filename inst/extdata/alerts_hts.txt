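# Promiscuous-binder / frequent-HTS-hitter substructure alerts.
# Format: name<TAB>SMARTS, one per line, '#' comments.
# Hand-written patterns covering the canonical PAINS / HTS-filter chemotype
# families; replace with an in-house catalog via load_catalog() as needed.
quinone	O=C1[#6]=[#6]C(=O)[#6]=[#6]1
catechol	[OX2H]c1ccccc1[OX2H]
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1C(=[#6])SC(=S)N1
michael_acceptor_enone	[C;!R]=[C;!R][CX3]=O
nitroaromatic	c[N+](=O)[O-]
azo_aromatic	cN=Nc
alkyl_halide_reactive	[CX4][Br,I]
thiourea	[NX3]C(=S)[NX3]
phenylhydrazone	[#6]=N[NX3]c1ccccc1
isothiazolone	O=[#6]1[#6]~[#6][#16][#7]1
beta_keto_phenol	[OX2H]c1ccccc1C(=O)[CH2]
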