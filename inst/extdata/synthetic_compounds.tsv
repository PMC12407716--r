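name	smiles
aspirin	CC(=O)Oc1ccccc1C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
ibuprofen	CC(C)Cc1ccc(C(C)C(=O)O)cc1
naproxen	COc1ccc2cc(C(C)C(=O)O)ccc2c1
diclofenac	O=C(O)Cc1ccccc1Nc1c(Cl)cccc1Cl
sulfamethoxazole	Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1
sulfanilamide	Nc1ccc(S(N)(=O)=O)cc1
phenytoin	O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1
barbital	CCC1(CC)C(=O)NC(=O)NC1=O
chlorpromazine	CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21
diazepam	CN1c2ccc(Cl)cc2C(c2ccccc2)=NCC1=O
haloperidol	O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1
fluoxetine	CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1
benzocaine	CCOC(=O)c1ccc(N)cc1
lidocaine	CCN(CC)CC(=O)Nc1c(C)cccc1C
procaine	CCN(CC)CCOC(=O)c1ccc(N)cc1
metformin	CN(C)C(=N)NC(=N)N
tolbutamide	CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1
warfarin	CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
DDT	Clc1ccc(C(c2ccc(Cl)cc2)C(Cl)(Cl)Cl)cc1
atrazine	CCNc1nc(Cl)nc(NC(C)C)n1
24-D	O=C(O)COc1ccc(Cl)cc1Cl
carbaryl	CNC(=O)Oc1cccc2ccccc12
parathion	CCOP(=S)(OCC)Oc1ccc([N+](=O)[O-])cc1
TNT	Cc1c([N+](=O)[O-])cc([N+](=O)[O-])cc1[N+](=O)[O-]
bisphenol-A	CC(C)(c1ccc(O)cc1)c1ccc(O)cc1
DEHP	CCCCC(CC)COC(=O)c1ccccc1C(=O)OCC(CC)CCCC
styrene	C=Cc1ccccc1
toluene	Cc1ccccc1
aniline	Nc1ccccc1
nitrobenzene	O=[N+]([O-])c1ccccc1
chlorobenzene	Clc1ccccc1
benzophenone	O=C(c1ccccc1)c1ccccc1
triclosan	Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl
saccharin	O=C1NS(=O)(=O)c2ccccc21
melamine	Nc1nc(N)nc(N)n1
EDTA	OC(=O)CN(CCN(CC(=O)O)CC(=O)O)CC(=O)O
propranolol	CC(C)NCC(O)COc1cccc2ccccc12
azobenzene	c1ccc(N=Nc2ccccc2)cc1
methylparaben	COC(=O)c1ccc(O)cc1
simazine	CCNc1nc(Cl)nc(NCC)n1
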