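# Seed solvent library: name<TAB>SMILES. Membership decides solvent-vs-reagent.
water	O
THF	C1CCOC1
DCM	ClCCl
chloroform	ClC(Cl)Cl
DMF	CN(C)C=O
DMSO	CS(C)=O
MeOH	CO
EtOH	CCO
iPrOH	CC(C)O
MeCN	CC#N
EtOAc	CCOC(C)=O
Et2O	CCOCC
dioxane	C1COCCO1
toluene	Cc1ccccc1
benzene	c1ccccc1
hexane	CCCCCC
DME	COCCOC
NMP	CN1CCCC1=O
acetone	CC(C)=O
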