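name	smiles	bits_hex
benzene	c1ccccc1	0000000000000000000040000000000000000000000000000000000000000000000000000000000000000010000000000000000000000000000000000000000000000000000000000000000000000000000100000000000002100000000000000000000000000000000000000000000000400000000000000000000000000000
cyclohexane	C1CCCCC1	0000000000000000000000000000000000000000000000000000000000000000080000000000000000000000000000008000000000040040000000000000000000000000000000000000000000000000000000020000000000000000000000000000000000000000000000000000000000000000000000000000008000000000
phenol	Oc1ccccc1	0000000000000000000040000000000000000000000000000000000000000000000000000000000000000010000000000000400000000000000000000000000010000000000000000000000040000000000100000000000002100000000000000000000000000040000000000000000000400000000000041000000000000000
quercetin	O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12	00000000024000820010418000060000020008102d005028000000010000021000021a000000000814100010000024000058410000400070021000400202600010450000040000001100040048210002000100820900000002100002008250400040010200000040040200013040800000408800008010041800040280040200
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	014000000000000300006200000200000000200000000006000004030000200020000c008200018402000008008000010000000000000200000110000000010030003000010014000000020000090000000000003001003005000001008002600000000000010000000300000200100000e08040000010000018010054000000
limonene	CC1=CCC(CC1)C(=C)C	0000000000004024000000000000000000000001004202000000000000000400080000000001000000000000000000008000000000040000040000000000000000000000002000000000000000004000000002020000000000000800000000004020000000000000000000000000800000000000000000000000008000000000
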