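# Monomer registry: one polymerizable unit per row.
# formula is the FREE monomer (with its own H2O); residue = formula - H2O.
# backbone_link is "ester" iff the alpha substituent is a hydroxyl
# (alpha hydroxy acids), "amide" otherwise.
# Formulas for 1-16 were derived from the compound names / synthesis routes
# and each cross-checked against a printed low-resolution ESI m/z where one
# exists (scaffold 148 [M+H]+; 8:228, 9:242, 10:256, 11:296, 13:188, 15:291,
# 16:215, all [M-H]-).
id	name	formula	backbone_link	side_chain_class
A	alanine	C3H7NO2	amide	canonical
R	arginine	C6H14N4O2	amide	canonical
N	asparagine	C4H8N2O3	amide	canonical
D	aspartate	C4H7NO4	amide	canonical
C	cysteine	C3H7NO2S	amide	canonical
E	glutamate	C5H9NO4	amide	canonical
Q	glutamine	C5H10N2O3	amide	canonical
G	glycine	C2H5NO2	amide	canonical
H	histidine	C6H9N3O2	amide	canonical
I	isoleucine	C6H13NO2	amide	canonical
L	leucine	C6H13NO2	amide	canonical
K	lysine	C6H14N2O2	amide	canonical
M	methionine	C5H11NO2S	amide	canonical
F	phenylalanine	C9H11NO2	amide	canonical
P	proline	C5H9NO2	amide	canonical
S	serine	C3H7NO3	amide	canonical
T	threonine	C4H9NO3	amide	canonical
W	tryptophan	C11H12N2O2	amide	canonical
Y	tyrosine	C9H11NO3	amide	canonical
V	valine	C5H11NO2	amide	canonical
1	AllocK (N6-allyloxycarbonyl-L-lysine)	C10H18N2O4	amide	aliphatic
2	AlkynK (N6-((prop-2-yn-1-yloxy)carbonyl)-L-lysine)	C10H16N2O4	amide	aliphatic
3	pIF (4-iodo-L-phenylalanine)	C9H10INO2	amide	aromatic
4	CbzK (N6-carbobenzyloxy-L-lysine)	C14H20N2O4	amide	aliphatic
5	pAzF (4-azido-L-phenylalanine)	C9H10N4O2	amide	aromatic
6	BocK-OH ((S)-6-(Boc-amino)-2-hydroxyhexanoic acid)	C11H21NO5	ester	aliphatic
7	AllocK-OH ((S)-6-(Alloc-amino)-2-hydroxyhexanoic acid)	C10H17NO5	ester	aliphatic
8	AlkynK-OH ((S)-6-(propargyloxycarbonylamino)-2-hydroxyhexanoic acid)	C10H15NO5	ester	aliphatic
9	ButK-OH ((S)-6-(but-3-yn-1-yloxycarbonylamino)-2-hydroxyhexanoic acid)	C11H17NO5	ester	aliphatic
10	PenK-OH ((S)-6-(pent-4-yn-1-yloxycarbonylamino)-2-hydroxyhexanoic acid)	C12H19NO5	ester	aliphatic
11	NorK-OH ((S)-6-((5-norbornene-2-yl)methoxycarbonylamino)-2-hydroxyhexanoic acid)	C15H23NO5	ester	aliphatic
12	CbzK-OH ((S)-6-(Cbz-amino)-2-hydroxyhexanoic acid)	C14H19NO5	ester	aliphatic
13	AcK-OH ((S)-6-acetamido-2-hydroxyhexanoic acid)	C8H15NO4	ester	aliphatic
14	F-OH ((S)-2-hydroxy-3-phenylpropanoic acid, phenyllactic acid)	C9H10O3	ester	aromatic
15	pIF-OH ((S)-2-hydroxy-3-(4-iodophenyl)propanoic acid)	C9H9IO3	ester	aromatic
16	NapA-OH ((S)-2-hydroxy-3-(naphthalen-2-yl)propanoic acid)	C13H12O3	ester	aromatic
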