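sample	134	140	240	296	305	314	338	351	368	465	512	533	625	637	647	653	663
A56	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0
A58	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	1
A60	0	1	0	0	0	0	0	0	1	0	1	0	1	0	1	0	0
A61	0	1	0	0	0	0	0	0	1	0	1	0	1	0	1	0	0
A67	1	0	1	0	1	1	0	1	0	0	0	0	1	0	0	1	0
A68	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0
A70	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0
A71	1	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0
A72	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
A73	0	0	0	0	0	0	0	0	0	0	1	1	1	0	1	0	0
A75	0	0	0	0	0	0	0	0	1	0	1	1	1	0	0	1	0
A76	1	0	1	0	1	1	0	1	0	0	0	0	1	0	0	1	0
A79	0	0	0	0	0	0	0	0	0	0	1	1	1	0	0	0	0
A82	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	1
A83	0	0	1	1	0	1	0	1	0	0	0	0	1	0	0	1	0
A87	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	1
A88	1	0	0	0	0	0	0	0	0	1	0	0	1	0	0	1	0
A90	0	0	0	0	0	0	1	0	0	0	1	1	1	1	1	0	0
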