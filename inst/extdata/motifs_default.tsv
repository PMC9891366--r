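name	smarts	add_h	notes
water	[OX2H2]	TRUE	isolated water molecule (O plus its two hydrogens)
carboxylic_acid	[CX3](=O)[OX2H1]	TRUE	-C(=O)OH
nitro	[$([NX3](=[OX1])=[OX1]),$([NX3+](=[OX1])[O-])]([!#8])	TRUE	N bonded to two terminal oxygens
nitroso	[NX2]=[OX1]	TRUE	-N=O
primary_amine	[NX3;H2;!$(N[C,S]=[O,S,N])][#6]	TRUE	-NH2 on carbon, amides excluded
amine	[NX3;H3,H2,H1;!$(N[C,S]=[O,S,N])]	TRUE	any N-H amine-like nitrogen (ammonia included)
carbonyl	[CX3]=[OX1]	TRUE	C=O
secondary_amine	[NX3;H1;!$(N[C,S]=[O,S,N])]([#6])[#6]	TRUE	R2NH, amides excluded
amide	[NX3][CX3](=[OX1])	TRUE	acetamide/amide core N-C=O
ether	[OD2;!$(O[C,S]=O)]([#6])[#6]	TRUE	C-O-C, esters excluded
methyl	[CX4H3]	TRUE	-CH3
ethyl	[CX4H2][CX4H3]	TRUE	-CH2CH3
alkane	[CX4;!$(C[O,N,S]);!$(C=*)]	TRUE	saturated carbon without heteroatom neighbors
alkene	[CX3]=[CX3]	TRUE	C=C
ring6_unsaturated	[#6]1~[#6]~[#6]~[#6]~[#6]~[#6]1	TRUE	6-membered unsaturated carbon ring (benzene-like, branched included)
triazole_123	c1cn[nH]n1	TRUE	1,2,3-triazole ring
triazole_124	c1nc[nH]n1	TRUE	1,2,4-triazole ring
tetrazole	c1nnn[nH]1	TRUE	tetrazole ring
pentazole	[nH]1nnnn1	TRUE	pentazole ring
imide	[CX3](=[OX1])[NX3][SX4](=[OX1])=[OX1]	TRUE	saccharin-type sulfonyl imide
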