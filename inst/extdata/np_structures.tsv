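name	smiles	pathway	superclass
limonene	CC1=CCC(CC1)C(=C)C	Terpenoids	Monoterpenoids
alpha-pinene	CC1=CCC2CC1C2(C)C	Terpenoids	Monoterpenoids
beta-myrcene	CC(=CCCC(=C)C=C)C	Terpenoids	Monoterpenoids
linalool	CC(=CCCC(C)(C=C)O)C	Terpenoids	Monoterpenoids
geraniol	CC(=CCCC(=CCO)C)C	Terpenoids	Monoterpenoids
menthol	CC(C)C1CCC(C)CC1O	Terpenoids	Monoterpenoids
camphor	CC1(C)C2CCC1(C)C(=O)C2	Terpenoids	Monoterpenoids
thymol	Cc1ccc(C(C)C)c(O)c1	Terpenoids	Monoterpenoids
carvacrol	Cc1ccc(C(C)C)cc1O	Terpenoids	Monoterpenoids
farnesol	CC(=CCCC(=CCCC(=CCO)C)C)C	Terpenoids	Sesquiterpenoids
nerolidol	CC(C)=CCCC(C)=CCCC(C)(O)C=C	Terpenoids	Sesquiterpenoids
beta-caryophyllene	CC1=CCCC(=C)C2CC(C)(C)C2CC1	Terpenoids	Sesquiterpenoids
alpha-humulene	CC1=CCC(C)(C)C=CCC(C)=CCC1	Terpenoids	Sesquiterpenoids
alpha-bisabolol	CC(C)=CCCC(C)C1(O)CCC(C)=CC1	Terpenoids	Sesquiterpenoids
germacrone	CC1=CCC(=CC(=O)C(=C(C)C)CC1)C	Terpenoids	Sesquiterpenoids
phytol	CC(C)CCCC(C)CCCC(C)CCCC(C)=CCO	Terpenoids	Diterpenoids
geranylgeraniol	CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C	Terpenoids	Diterpenoids
squalene	CC(=CCCC(=CCCC(=CCCC=C(C)CCC=C(C)CCC=C(C)C)C)C)C	Terpenoids	Triterpenoids
beta-sitosterol	CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C)C(C)C	Terpenoids	Steroids
beta-ionone	CC(=O)C=CC1=C(C)CCCC1(C)C	Terpenoids	Apocarotenoids
quercetin	O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	Shikimates and Phenylpropanoids	Flavonoids
kaempferol	O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12	Shikimates and Phenylpropanoids	Flavonoids
apigenin	O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12	Shikimates and Phenylpropanoids	Flavonoids
luteolin	O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	Shikimates and Phenylpropanoids	Flavonoids
naringenin	O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21	Shikimates and Phenylpropanoids	Flavonoids
catechin	Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2	Shikimates and Phenylpropanoids	Flavonoids
caffeic-acid	O=C(O)C=Cc1ccc(O)c(O)c1	Shikimates and Phenylpropanoids	Phenylpropanoids (C6-C3)
ferulic-acid	COc1cc(C=CC(=O)O)ccc1O	Shikimates and Phenylpropanoids	Phenylpropanoids (C6-C3)
p-coumaric-acid	O=C(O)C=Cc1ccc(O)cc1	Shikimates and Phenylpropanoids	Phenylpropanoids (C6-C3)
cinnamic-acid	O=C(O)C=Cc1ccccc1	Shikimates and Phenylpropanoids	Phenylpropanoids (C6-C3)
eugenol	C=CCc1ccc(O)c(OC)c1	Shikimates and Phenylpropanoids	Phenylpropanoids (C6-C3)
coumarin	O=c1ccc2ccccc2o1	Shikimates and Phenylpropanoids	Coumarins
umbelliferone	O=c1ccc2ccc(O)cc2o1	Shikimates and Phenylpropanoids	Coumarins
scopoletin	COc1cc2ccc(=O)oc2cc1O	Shikimates and Phenylpropanoids	Coumarins
esculetin	Oc1cc2oc(=O)ccc2cc1O	Shikimates and Phenylpropanoids	Coumarins
gallic-acid	O=C(O)c1cc(O)c(O)c(O)c1	Shikimates and Phenylpropanoids	Phenolic acids (C6-C1)
vanillin	COc1cc(C=O)ccc1O	Shikimates and Phenylpropanoids	Phenolic acids (C6-C1)
vanillic-acid	COc1cc(C(=O)O)ccc1O	Shikimates and Phenylpropanoids	Phenolic acids (C6-C1)
salicylic-acid	O=C(O)c1ccccc1O	Shikimates and Phenylpropanoids	Phenolic acids (C6-C1)
syringic-acid	COc1cc(C(=O)O)cc(OC)c1O	Shikimates and Phenylpropanoids	Phenolic acids (C6-C1)
resveratrol	Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1	Shikimates and Phenylpropanoids	Stilbenoids
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	Alkaloids	Pseudoalkaloids
nicotine	CN1CCCC1c1cccnc1	Alkaloids	Nicotinic acid alkaloids
trigonelline	C[n+]1cccc(C(=O)[O-])c1	Alkaloids	Nicotinic acid alkaloids
anabasine	C1CCC(NC1)c1cccnc1	Alkaloids	Nicotinic acid alkaloids
serotonin	NCCc1c[nH]c2ccc(O)cc12	Alkaloids	Tryptophan alkaloids
tryptamine	NCCc1c[nH]c2ccccc12	Alkaloids	Tryptophan alkaloids
harmane	Cc1nccc2c1[nH]c1ccccc12	Alkaloids	Tryptophan alkaloids
gramine	CN(C)Cc1c[nH]c2ccccc12	Alkaloids	Tryptophan alkaloids
3-indoleacrylic-acid	O=C(O)C=Cc1c[nH]c2ccccc12	Alkaloids	Tryptophan alkaloids
hordenine	CN(C)CCc1ccc(O)cc1	Alkaloids	Tyrosine alkaloids
tyramine	NCCc1ccc(O)cc1	Alkaloids	Tyrosine alkaloids
piperine	O=C(C=CC=Cc1ccc2c(c1)OCO2)N1CCCCC1	Alkaloids	Lysine alkaloids
lupinine	OCC1CCCN2CCCCC12	Alkaloids	Lysine alkaloids
anthranilic-acid	Nc1ccccc1C(=O)O	Alkaloids	Anthranilic acid alkaloids
tryptophan	NC(Cc1c[nH]c2ccccc12)C(=O)O	Amino acids and Peptides	Amino acids
tyrosine	NC(Cc1ccc(O)cc1)C(=O)O	Amino acids and Peptides	Amino acids
phenylalanine	NC(Cc1ccccc1)C(=O)O	Amino acids and Peptides	Amino acids
asparagine	NC(=O)CC(N)C(=O)O	Amino acids and Peptides	Amino acids
proline	OC(=O)C1CCCN1	Amino acids and Peptides	Amino acids
glutamine	NC(CCC(N)=O)C(=O)O	Amino acids and Peptides	Amino acids
leucine	CC(C)CC(N)C(=O)O	Amino acids and Peptides	Amino acids
glutathione	NC(CCC(=O)NC(CS)C(=O)NCC(=O)O)C(=O)O	Amino acids and Peptides	Small peptides
emodin	Cc1cc2c(c(O)c1)C(=O)c1cc(O)cc(O)c1C2=O	Polyketides	Anthraquinones
6-methylsalicylic-acid	Cc1cccc(O)c1C(=O)O	Polyketides	Phenolic polyketides
curcumin	COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O	Polyketides	Diarylheptanoids
phloroglucinol	Oc1cc(O)cc(O)c1	Polyketides	Phloroglucinols
palmitic-acid	CCCCCCCCCCCCCCCC(=O)O	Fatty acids	Saturated fatty acids
oleic-acid	CCCCCCCCC=CCCCCCCCC(=O)O	Fatty acids	Unsaturated fatty acids
linoleic-acid	CCCCCC=CCC=CCCCCCCCC(=O)O	Fatty acids	Unsaturated fatty acids
lauric-acid	CCCCCCCCCCCC(=O)O	Fatty acids	Saturated fatty acids
glucose	OCC1OC(O)C(O)C(O)C1O	Carbohydrates	Monosaccharides
sucrose	OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O	Carbohydrates	Disaccharides
myo-inositol	OC1C(O)C(O)C(O)C(O)C1O	Carbohydrates	Cyclitols
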