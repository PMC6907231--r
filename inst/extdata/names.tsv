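# Seed name library: key<TAB>SMILES[<TAB>source]; source one of internal/corpus/editor.
DMF	CN(C)C=O	internal
DMSO	CS(C)=O	internal
THF	C1CCOC1	internal
2-MeTHF	CC1CCCO1	corpus
DCM	ClCCl	internal
chloroform	ClC(Cl)Cl	internal
MeOH	CO	internal
EtOH	CCO	internal
iPrOH	CC(C)O	internal
n-BuOH	CCCCO	corpus
MeCN	CC#N	internal
EtOAc	CCOC(C)=O	internal
Et2O	CCOCC	internal
MTBE	COC(C)(C)C	corpus
dioxane	C1COCCO1	internal
toluene	Cc1ccccc1	internal
benzene	c1ccccc1	internal
xylene	Cc1ccccc1C	editor
hexane	CCCCCC	internal
pentane	CCCCC	corpus
heptane	CCCCCCC	corpus
cyclohexane	C1CCCCC1	internal
DME	COCCOC	internal
diglyme	COCCOCCOC	corpus
NMP	CN1CCCC1=O	internal
DMA	CC(=O)N(C)C	internal
acetone	CC(C)=O	internal
water	O	internal
brine	O.[Na+].[Cl-]	internal
pyridine	c1ccncc1	internal
NEt3	CCN(CC)CC	internal
Et3N	CCN(CC)CC	internal
TEA	CCN(CC)CC	editor
DIPEA	CCN(C(C)C)C(C)C	internal
DBU	C1CCC2=NCCCN2CC1	internal
DMAP	CN(C)c1ccncc1	internal
NaH	[Na+].[H-]	internal
NaOH	[Na+].[OH-]	internal
KOH	[K+].[OH-]	internal
LiOH	[Li+].[OH-]	internal
K2CO3	[K+].[K+].[O-]C([O-])=O	internal
Cs2CO3	[Cs+].[Cs+].[O-]C([O-])=O	internal
Na2CO3	[Na+].[Na+].[O-]C([O-])=O	internal
NaHCO3	[Na+].OC([O-])=O	internal
KOtBu	[K+].[O-]C(C)(C)C	internal
NaOMe	[Na+].[O-]C	internal
n-BuLi	[Li]CCCC	internal
LDA	[Li+].[N-](C(C)C)C(C)C	internal
TFA	OC(=O)C(F)(F)F	internal
AcOH	CC(O)=O	internal
HCl	Cl	internal
H2SO4	OS(O)(=O)=O	internal
HNO3	O[N+]([O-])=O	internal
NH4Cl	[NH4+].[Cl-]	internal
NaCl	[Na+].[Cl-]	internal
Na2SO4	[Na+].[Na+].[O-]S([O-])(=O)=O	internal
MgSO4	[Mg+2].[O-]S([O-])(=O)=O	internal
Pd/C	[Pd]	internal
Pd(OAc)2	CC(=O)O[Pd]OC(C)=O	internal
PPh3	c1ccc(cc1)P(c2ccccc2)c3ccccc3	internal
TsOH	Cc1ccc(cc1)S(O)(=O)=O	internal
MsCl	CS(Cl)(=O)=O	internal
TsCl	Cc1ccc(cc1)S(Cl)(=O)=O	internal
SOCl2	ClS(Cl)=O	internal
NBS	O=C1CCC(=O)N1Br	internal
NCS	O=C1CCC(=O)N1Cl	internal
AIBN	N#CC(C)(C)N=NC(C)(C)C#N	internal
mCPBA	OOC(=O)c1cccc(Cl)c1	internal
H2O2	OO	internal
NaBH4	[Na+].[BH4-]	internal
LiAlH4	[Li+].[AlH4-]	internal
MeI	CI	internal
morpholine	C1COCCN1	internal
piperidine	C1CCNCC1	internal
imidazole	c1cnc[nH]1	internal
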