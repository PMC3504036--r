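sample	accD_216	accD_335	accD_560	accD_644	accD_797	accD_858	accD_1058	accD_1177	accD_1275	matK_201	matK_822	matK_889	matK_934	matK_1031	matK_1132	rbcL_66
B11	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B12	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B14	1	0	1	1	0	0	0	0	0	0	1	1	1	0	1	1
B25	0	0	1	1	0	0	0	0	0	0	0	0	0	0	1	0
B27	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B29	0	0	1	1	0	0	0	0	0	0	1	1	1	0	1	0
B32	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B45	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	0
B51	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B60	1	0	1	1	0	0	0	0	0	0	1	1	1	0	1	1
B64	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B65	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B66	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B68	0	0	0	0	0	0	0	0	0	0	1	1	0	0	1	1
B69	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	0
B73	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B74	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B76	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B79	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	0
B81	0	0	0	1	0	0	0	0	0	0	1	1	0	0	1	1
B90	1	0	1	1	0	0	0	0	0	0	1	1	1	0	1	1
B91	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B92	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B93	0	0	1	1	0	0	0	0	0	0	1	1	0	0	1	1
B94	0	1	0	0	1	1	1	1	1	1	1	0	0	1	1	0
B95	0	1	0	0	1	1	1	1	1	1	1	0	0	1	1	0
B96	0	1	0	0	1	1	1	1	1	1	1	0	0	1	1	0
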