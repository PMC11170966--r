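group_name	category	smarts	rarity
hydroxamate	searchable	[CX3](=[OX1])[NX3][OX2H1]	common
cyclic hydroxamate	searchable	[OX2H1][#7X3]1[#6X3](=[OX1])[#6]~[#6]~[#6]~[#6]1	rare
catecholate	searchable	[OX2H1]c1ccccc1[OX2H1]	common
phenolate	searchable	[OX2H1]c1ccccc1[CX3]=[OX1]	common
hydroxyphenyloxazoline	searchable	[OX2H1]c1ccccc1C2=NCCO2	rare
hydroxyphenylthiazoline	searchable	[OX2H1]c1ccccc1C2=NCCS2	rare
hydroxyphenyloxazole	searchable	[OX2H1]c1ccccc1-c2ncco2	rare
hydroxyphenylthiazole	searchable	[OX2H1]c1ccccc1-c2nccs2	rare
alpha-aminocarboxylate	searchable	[NX3;H1,H2;!$([NX3][CX3]=[OX1])][CX4][CX3](=[OX1])[OX2H1]	common
alpha-hydroxyimidazole	searchable	[OX2H1][CX4]c1nccn1	rare
diazeniumdiolate	searchable	[OX2H1][NX3][NX2]=[OX1]	rare
2-nitrosophenol	searchable	[OX2H1]c1ccccc1[NX2]=[OX1]	rare
carboxylate-in-citrate	searchable	[OX2H1][CX3](=[OX1])[CX4]([OX2H1])([CH2X4][CX3](=[OX1])[NX3])[CH2X4][CX3]=[OX1]	common
alpha-hydroxycarboxylate-in-citrate	searchable	[OX2H1][CX4]([CX3](=[OX1])[OX2H1])([CH2X4][CX3](=[OX1])[NX3])[CH2X4][CX3]=[OX1]	common
8-hydroxyquinoline	searchable	[OX2H1]c1cccc2cccnc12	rare
alpha-hydroxycarboxylate	common_excluded	[OX2H1][CX4][CX3](=[OX1])[OX2H1]	common
carboxylate	common_excluded	[CX3](=[OX1])[OX2H1]	common
O-alkyl-hydroxamate	modified_veto	[CX3](=[OX1])[NX3][OX2][CX4]	rare
O-acyl-hydroxamate	modified_veto	[CX3](=[OX1])[NX3][OX2][CX3]=[OX1]	rare
O-alkyl-catecholate	modified_veto	[CX4][OX2]c1ccccc1[OX2]	rare
O-acyl-catecholate	modified_veto	[OX1]=[CX3][OX2]c1ccccc1[OX2]	rare
O-alkyl-phenolate	modified_veto	[CX4][OX2]c1ccccc1[CX3]=[OX1]	rare
O-acyl-phenolate	modified_veto	[OX1]=[CX3][OX2]c1ccccc1[CX3]=[OX1]	rare
O-alkyl-hydroxyphenylazoline	modified_veto	[CX4][OX2]c1ccccc1[CX3]2=[NX2][CX4][CX4][O,S]2	rare
O-alkyl-2-nitrosophenol	modified_veto	[CX4][OX2]c1ccccc1[NX2]=[OX1]	rare
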