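# Seed superatom library: key<TAB>expansion SMILES with [*] attachment markers.
# Subset of the curated library; full-size files in the same format load identically.
Me	[*]C
Et	[*]CC
nPr	[*]CCC
iPr	[*]C(C)C
nBu	[*]CCCC
tBu	[*]C(C)(C)C
Ph	[*]c1ccccc1
Bn	[*]Cc1ccccc1
Bz	[*]C(=O)c1ccccc1
Ac	[*]C(C)=O
Boc	[*]C(=O)OC(C)(C)C
Cbz	[*]C(=O)OCc1ccccc1
Ts	[*]S(=O)(=O)c1ccc(C)cc1
Ms	[*]S(C)(=O)=O
Tf	[*]S(=O)(=O)C(F)(F)F
OMe	[*]OC
OEt	[*]OCC
OiPr	[*]OC(C)C
OtBu	[*]OC(C)(C)C
OBn	[*]OCc1ccccc1
OAc	[*]OC(C)=O
OTs	[*]OS(=O)(=O)c1ccc(C)cc1
OMs	[*]OS(C)(=O)=O
CN	[*]C#N
NO2	[*][N+](=O)[O-]
CO2H	[*]C(=O)O
CO2Me	[*]C(=O)OC
CO2Et	[*]C(=O)OCC
CHO	[*]C=O
CF3	[*]C(F)(F)F
CCl3	[*]C(Cl)(Cl)Cl
NMe2	[*]N(C)C
NEt2	[*]N(CC)CC
NHMe	[*]NC
NHAc	[*]NC(C)=O
NHBoc	[*]NC(=O)OC(C)(C)C
SMe	[*]SC
SPh	[*]Sc1ccccc1
TMS	[*][Si](C)(C)C
TBS	[*][Si](C)(C)C(C)(C)C
SO2	[*]S([*])(=O)=O
CH2	[*]C[*]
CH2CH2	[*]CC[*]
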