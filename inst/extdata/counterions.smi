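# Common counter-ions / salt partners, one SMILES per line (optional name).
# Both charged and neutral protonation variants are listed where relevant;
# matching is by canonical SMILES of the stripped fragment.
[Cl-]	chloride
Cl	hydrogen_chloride
[Br-]	bromide
Br	hydrogen_bromide
[I-]	iodide
I	hydrogen_iodide
[F-]	fluoride
[Na+]	sodium
[K+]	potassium
[Li+]	lithium
[Ca+2]	calcium
[Mg+2]	magnesium
[Zn+2]	zinc
[NH4+]	ammonium
N	ammonia
O	water
CC(=O)O	acetic_acid
CC(=O)[O-]	acetate
OC(=O)C(F)(F)F	trifluoroacetic_acid
[O-]C(=O)C(F)(F)F	trifluoroacetate
OC(=O)C(=O)O	oxalic_acid
[O-]C(=O)C(=O)[O-]	oxalate
OC(=O)C=CC(=O)O	maleic_fumaric_acid
OC(=O)C(O)C(O)C(=O)O	tartaric_acid
OC(=O)CC(O)(CC(=O)O)C(=O)O	citric_acid
CS(=O)(=O)O	methanesulfonic_acid
CS(=O)(=O)[O-]	methanesulfonate
Cc1ccc(cc1)S(=O)(=O)O	toluenesulfonic_acid
Cc1ccc(cc1)S(=O)(=O)[O-]	tosylate
OS(=O)(=O)O	sulfuric_acid
OS(=O)(=O)[O-]	hydrogensulfate
[O-]S(=O)(=O)[O-]	sulfate
O[N+](=O)[O-]	nitric_acid
[O-][N+](=O)[O-]	nitrate
OP(=O)(O)O	phosphoric_acid
OP(=O)(O)[O-]	dihydrogenphosphate
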