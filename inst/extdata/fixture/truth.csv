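"feature_id","role","true_log2fc","pathway","superclass","smiles","in_reference"
"F0001","null",0,"Amino acids and Peptides","Amino acids","OC(=O)C1CCCN1",FALSE
"F0002","null",0,"Amino acids and Peptides","Amino acids","OC(=O)C1CCCN1",FALSE
"F0003","null",0,"Shikimates and Phenylpropanoids","Phenylpropanoids (C6-C3)","C=CCc1ccc(O)c(OC)c1",FALSE
"F0004","null",0,"Alkaloids","Tryptophan alkaloids","NCCc1c[nH]c2ccccc12",FALSE
"F0005","null",0,"Alkaloids","Nicotinic acid alkaloids","C1CCC(NC1)c1cccnc1",FALSE
"F0006","null",0,"Polyketides","Phenolic polyketides","Cc1cccc(O)c1C(=O)O",TRUE
"F0007","null",0,"Amino acids and Peptides","Amino acids","NC(=O)CC(N)C(=O)O",FALSE
"F0008","null",0,"Terpenoids","Monoterpenoids","CC(=CCCC(C)(C=C)O)C",FALSE
"F0009","null",0,"Amino acids and Peptides","Amino acids","NC(Cc1c[nH]c2ccccc12)C(=O)O",FALSE
"F0010","null",0,"Shikimates and Phenylpropanoids","Flavonoids","O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",FALSE
"F0011","null",0,"Shikimates and Phenylpropanoids","Flavonoids","Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2",FALSE
"F0012","null",0,"Terpenoids","Apocarotenoids","CC(=O)C=CC1=C(C)CCCC1(C)C",FALSE
"F0013","method_enriched_extract",-3,"Terpenoids","Steroids","CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C)C(C)C",FALSE
"F0014","method_enriched_juice",3,"Polyketides","Diarylheptanoids","COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O",TRUE
"F0015","organ_enriched_seed",3,"Terpenoids","Sesquiterpenoids","CC(=CCCC(=CCCC(=CCO)C)C)C",TRUE
"F0016","organ_enriched_root",-3,"Amino acids and Peptides","Amino acids","NC(=O)CC(N)C(=O)O",FALSE
"F0017","null",0,"Polyketides","Diarylheptanoids","COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O",TRUE
"F0018","subfloor",0,"Alkaloids","Lysine alkaloids","O=C(C=CC=Cc1ccc2c(c1)OCO2)N1CCCCC1",FALSE
"F0019","null",0,"Polyketides","Phloroglucinols","Oc1cc(O)cc(O)c1",TRUE
"F0020","null",0,"Shikimates and Phenylpropanoids","Flavonoids","O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",FALSE
"F0021","organ_enriched_root",-3,"Terpenoids","Steroids","CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C)C(C)C",FALSE
"F0022","null",0,"Terpenoids","Sesquiterpenoids","CC1=CCC(=CC(=O)C(=C(C)C)CC1)C",FALSE
"F0023","null",0,"Terpenoids","Sesquiterpenoids","CC1=CCC(C)(C)C=CCC(C)=CCC1",FALSE
"F0024","null",0,"Shikimates and Phenylpropanoids","Coumarins","O=c1ccc2ccc(O)cc2o1",FALSE
"F0025","null",0,"Terpenoids","Monoterpenoids","CC(=CCCC(C)(C=C)O)C",FALSE
"F0026","null",0,"Terpenoids","Sesquiterpenoids","CC1=CCC(C)(C)C=CCC(C)=CCC1",FALSE
"F0027","null",0,"Terpenoids","Diterpenoids","CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C",FALSE
"F0028","null",0,"Shikimates and Phenylpropanoids","Stilbenoids","Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1",TRUE
"F0029","null",0,"Amino acids and Peptides","Amino acids","NC(CCC(N)=O)C(=O)O",FALSE
"F0030","method_enriched_extract",-3,"Shikimates and Phenylpropanoids","Flavonoids","Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2",FALSE
"F0031","null",0,"Alkaloids","Anthranilic acid alkaloids","Nc1ccccc1C(=O)O",FALSE
"F0032","null",0,"Polyketides","Anthraquinones","Cc1cc2c(c(O)c1)C(=O)c1cc(O)cc(O)c1C2=O",FALSE
"F0033","null",0,"Alkaloids","Tryptophan alkaloids","NCCc1c[nH]c2ccccc12",FALSE
"F0034","subfloor",0,"Fatty acids","Saturated fatty acids","CCCCCCCCCCCC(=O)O",FALSE
"F0035","subfloor",0,"Amino acids and Peptides","Amino acids","NC(=O)CC(N)C(=O)O",FALSE
"F0036","null",0,"Shikimates and Phenylpropanoids","Flavonoids","O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",FALSE
"F0037","null",0,"Terpenoids","Monoterpenoids","CC(=CCCC(=C)C=C)C",FALSE
"F0038","null",0,"Terpenoids","Diterpenoids","CC(C)CCCC(C)CCCC(C)CCCC(C)=CCO",FALSE
"F0039","method_enriched_juice",3,"Terpenoids","Sesquiterpenoids","CC1=CCCC(=C)C2CC(C)(C)C2CC1",FALSE
"F0040","null",0,"Terpenoids","Diterpenoids","CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C",FALSE
"F0041","null",0,"Alkaloids","Nicotinic acid alkaloids","C[n+]1cccc(C(=O)[O-])c1",FALSE
"F0042","null",0,"Amino acids and Peptides","Amino acids","NC(Cc1c[nH]c2ccccc12)C(=O)O",FALSE
"F0043","null",0,"Shikimates and Phenylpropanoids","Phenylpropanoids (C6-C3)","O=C(O)C=Cc1ccc(O)cc1",FALSE
"F0044","null",0,"Shikimates and Phenylpropanoids","Phenolic acids (C6-C1)","COc1cc(C=O)ccc1O",FALSE
"F0045","method_enriched_juice",3,"Alkaloids","Pseudoalkaloids","Cn1cnc2c1c(=O)n(C)c(=O)n2C",FALSE
"F0046","organ_enriched_root",-3,"Terpenoids","Diterpenoids","CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C",FALSE
"F0047","method_enriched_juice",3,"Terpenoids","Monoterpenoids","CC(=CCCC(=C)C=C)C",FALSE
"F0048","null",0,"Shikimates and Phenylpropanoids","Phenolic acids (C6-C1)","COc1cc(C(=O)O)ccc1O",FALSE
"F0049","organ_enriched_seed",3,"Terpenoids","Monoterpenoids","CC1(C)C2CCC1(C)C(=O)C2",FALSE
"F0050","organ_enriched_root",-3,"Terpenoids","Sesquiterpenoids","CC(=CCCC(=CCCC(=CCO)C)C)C",TRUE
"F0051","null",0,"Terpenoids","Monoterpenoids","CC(=CCCC(=CCO)C)C",FALSE
"F0052","contaminant",0,"Alkaloids","Tryptophan alkaloids","O=C(O)C=Cc1c[nH]c2ccccc12",TRUE
"F0053","null",0,"Terpenoids","Sesquiterpenoids","CC(=CCCC(=CCCC(=CCO)C)C)C",TRUE
"F0054","null",0,"Terpenoids","Steroids","CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C)C(C)C",FALSE
"F0055","contaminant",0,"Alkaloids","Tyrosine alkaloids","CN(C)CCc1ccc(O)cc1",FALSE
"F0056","null",0,"Shikimates and Phenylpropanoids","Phenolic acids (C6-C1)","COc1cc(C(=O)O)ccc1O",FALSE
"F0057","null",0,"Shikimates and Phenylpropanoids","Flavonoids","O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",TRUE
"F0058","method_enriched_extract",-3,"Shikimates and Phenylpropanoids","Phenylpropanoids (C6-C3)","O=C(O)C=Cc1ccc(O)cc1",FALSE
"F0059","contaminant",0,"Terpenoids","Sesquiterpenoids","CC1=CCCC(=C)C2CC(C)(C)C2CC1",FALSE
"F0060","organ_enriched_seed",3,"Terpenoids","Sesquiterpenoids","CC(=CCCC(=CCCC(=CCO)C)C)C",TRUE
"F0061","organ_enriched_seed",3,"Shikimates and Phenylpropanoids","Flavonoids","O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",TRUE
"F0062","null",0,"Carbohydrates","Disaccharides","OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",FALSE
"F0063","null",0,"Terpenoids","Monoterpenoids","CC1=CCC(CC1)C(=C)C",FALSE
"F0064","null",0,"Fatty acids","Unsaturated fatty acids","CCCCCCCCC=CCCCCCCCC(=O)O",FALSE
"F0065","null",0,"Polyketides","Diarylheptanoids","COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O",TRUE
"F0066","null",0,"Alkaloids","Anthranilic acid alkaloids","Nc1ccccc1C(=O)O",FALSE
"F0067","organ_enriched_root",-3,"Shikimates and Phenylpropanoids","Coumarins","COc1cc2ccc(=O)oc2cc1O",FALSE
"F0068","null",0,"Shikimates and Phenylpropanoids","Phenolic acids (C6-C1)","COc1cc(C(=O)O)cc(OC)c1O",FALSE
"F0069","contaminant",0,"Terpenoids","Monoterpenoids","CC(=CCCC(=CCO)C)C",FALSE
"F0070","null",0,"Alkaloids","Pseudoalkaloids","Cn1cnc2c1c(=O)n(C)c(=O)n2C",FALSE
"F0071","null",0,"Alkaloids","Tryptophan alkaloids","Cc1nccc2c1[nH]c1ccccc12",FALSE
"F0072","organ_enriched_seed",3,"Shikimates and Phenylpropanoids","Phenolic acids (C6-C1)","O=C(O)c1ccccc1O",TRUE
"F0073","null",0,"Terpenoids","Apocarotenoids","CC(=O)C=CC1=C(C)CCCC1(C)C",FALSE
"F0074","null",0,"Terpenoids","Diterpenoids","CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C",FALSE
"F0075","null",0,"Terpenoids","Diterpenoids","CC(=CCCC(=CCCC(=CCCC(=CCO)C)C)C)C",FALSE
"F0076","method_enriched_extract",-3,"Shikimates and Phenylpropanoids","Phenylpropanoids (C6-C3)","O=C(O)C=Cc1ccccc1",TRUE
"F0077","subfloor",0,"Terpenoids","Steroids","CCC(CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC21C)C(C)C",FALSE
"F0078","organ_enriched_root",-3,"Terpenoids","Monoterpenoids","CC1=CCC(CC1)C(=C)C",FALSE
"F0079","null",0,"Terpenoids","Monoterpenoids","Cc1ccc(C(C)C)c(O)c1",FALSE
"F0080","organ_enriched_seed",3,"Fatty acids","Unsaturated fatty acids","CCCCCC=CCC=CCCCCCCCC(=O)O",FALSE
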