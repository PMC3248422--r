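# compounds by number of pathway-class labels in the two benchmark sets
n_labels	group1	group2
1	4027	2820
2	246	226
3	54	53
4	24	23
5	9	9
6	4	4
7	2	2
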