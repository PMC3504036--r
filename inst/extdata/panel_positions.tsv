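column_id	gene	position	kind	ref	alt
accD_216	accD	216	substitution	G	T
accD_335	accD	335	substitution	T	A
accD_560	accD	560	deletion	AAAGTG	.
accD_644	accD	644	substitution	A	C
accD_797	accD	797	substitution	C	T
accD_858	accD	858	substitution	G	A
accD_1058	accD	1058	substitution	G	A
accD_1177	accD	1177	substitution	T	G
accD_1275	accD	1275	substitution	T	C
matK_201	matK	201	substitution	A	G
matK_822	matK	822	substitution	T	A
matK_889	matK	889	substitution	T	G
matK_934	matK	934	substitution	G	A
matK_1031	matK	1031	substitution	TT	AA
matK_1132	matK	1132	substitution	G	T
rbcL_66	rbcL	66	substitution	G	A
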