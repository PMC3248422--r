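# per-class compound counts of the annotated (group1) and interacting (group2) benchmark sets
class_code	name	group1	group2
1	Carbohydrate Metabolism	444	394
2	Energy Metabolism	129	120
3	Lipid Metabolism	610	383
4	Nucleotide Metabolism	145	132
5	Amino Acid Metabolism	563	483
6	Metabolism of Other Amino Acids	212	154
7	Glycan Biosynthesis and Metabolism	68	43
8	Metabolism of Cofactors and Vitamins	396	309
9	Metabolism of Terpenoids and Polyketides	713	499
10	Biosynthesis of Other Secondary Metabolites	722	519
11	Xenobiotics Biodegradation and Metabolism	858	570
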