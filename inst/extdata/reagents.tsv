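# Seed reagent drop-down list: display name<TAB>SMILES.
NEt3	CCN(CC)CC
DIPEA	CCN(C(C)C)C(C)C
DBU	C1CCC2=NCCCN2CC1
DMAP	CN(C)c1ccncc1
K2CO3	[K+].[K+].[O-]C([O-])=O
Cs2CO3	[Cs+].[Cs+].[O-]C([O-])=O
NaH	[Na+].[H-]
NaOH	[Na+].[OH-]
KOtBu	[K+].[O-]C(C)(C)C
n-BuLi	[Li]CCCC
LDA	[Li+].[N-](C(C)C)C(C)C
TFA	OC(=O)C(F)(F)F
AcOH	CC(O)=O
HCl	Cl
Pd/C	[Pd]
Pd(OAc)2	CC(=O)O[Pd]OC(C)=O
PPh3	c1ccc(cc1)P(c2ccccc2)c3ccccc3
TsOH	Cc1ccc(cc1)S(O)(=O)=O
TsCl	Cc1ccc(cc1)S(Cl)(=O)=O
MsCl	CS(Cl)(=O)=O
SOCl2	ClS(Cl)=O
NBS	O=C1CCC(=O)N1Br
mCPBA	OOC(=O)c1cccc(Cl)c1
NaBH4	[Na+].[BH4-]
LiAlH4	[Li+].[AlH4-]
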