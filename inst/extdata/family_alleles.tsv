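gene	position	sample	allele	is_reference	detected
accD	56	A64	C	1	NP
accD	56	A65	T	0	0
accD	56	A67	T	0	0
accD	56	A68	T	0	0
accD	56	A69	T	0	0
accD	63	A64	A	1	NP
accD	63	A65	A	0	NP
accD	63	A67	A	0	NP
accD	63	A68	G	0	0
accD	63	A69	G	0	0
accD	73	A64	G	1	NP
accD	73	A65	G	0	NP
accD	73	A67	G	0	NP
accD	73	A68	A	0	1
accD	73	A69	G	0	NP
accD	74	A64	T	1	NP
accD	74	A65	C	0	0
accD	74	A67	C	0	0
accD	74	A68	C	0	0
accD	74	A69	C	0	0
accD	81	A64	T	1	NP
accD	81	A65	T	0	NP
accD	81	A67	T	0	NP
accD	81	A68	G	0	0
accD	81	A69	G	0	0
accD	86	A64	G	1	NP
accD	86	A65	A	0	1
accD	86	A67	G	0	NP
accD	86	A68	G	0	NP
accD	86	A69	G	0	NP
accD	87	A64	A	1	NP
accD	87	A65	C	0	1
accD	87	A67	A	0	NP
accD	87	A68	A	0	NP
accD	87	A69	A	0	NP
accD	88	A64	T	1	NP
accD	88	A65	A	0	1
accD	88	A67	T	0	NP
accD	88	A68	T	0	NP
accD	88	A69	T	0	NP
accD	100	A64	G	1	NP
accD	100	A65	T	0	1
accD	100	A67	G	0	NP
accD	100	A68	G	0	NP
accD	100	A69	G	0	NP
accD	109	A64	G	1	NP
accD	109	A65	G	0	NP
accD	109	A67	G	0	NP
accD	109	A68	A	0	0
accD	109	A69	A	0	0
accD	119	A64	A	1	NP
accD	119	A65	G	0	1
accD	119	A67	G	0	1
accD	119	A68	G	0	1
accD	119	A69	G	0	1
accD	127	A64	A	1	NP
accD	127	A65	G	0	1
accD	127	A67	A	0	NP
accD	127	A68	A	0	NP
accD	127	A69	A	0	NP
accD	134	A64	C	1	NP
accD	134	A65	A	0	1
accD	134	A67	C	0	NP
accD	134	A68	C	0	NP
accD	134	A69	C	0	NP
accD	135	A64	G	1	NP
accD	135	A65	T	0	1
accD	135	A67	G	0	NP
accD	135	A68	G	0	NP
accD	135	A69	G	0	NP
accD	144	A64	C	1	NP
accD	144	A65	A	0	1
accD	144	A67	C	0	NP
accD	144	A68	A	0	1
accD	144	A69	A	0	1
accD	151	A64	A	1	NP
accD	151	A65	C	0	1
accD	151	A67	A	0	NP
accD	151	A68	A	0	NP
accD	151	A69	A	0	NP
accD	152	A64	C	1	NP
accD	152	A65	T	0	1
accD	152	A67	C	0	NP
accD	152	A68	C	0	NP
accD	152	A69	C	0	NP
accD	187	A64	G	1	NP
accD	187	A65	T	0	1
accD	187	A67	G	0	NP
accD	187	A68	G	0	NP
accD	187	A69	G	0	NP
accD	191	A64	A	1	NP
accD	191	A65	G	0	1
accD	191	A67	A	0	NP
accD	191	A68	A	0	NP
accD	191	A69	A	0	NP
accD	207	A64	A	1	NP
accD	207	A65	A	0	NP
accD	207	A67	A	0	NP
accD	207	A68	G	0	1
accD	207	A69	G	0	1
accD	225	A64	C	1	NP
accD	225	A65	C	0	NP
accD	225	A67	C	0	NP
accD	225	A68	G	0	1
accD	225	A69	G	0	1
accD	227	A64	A	1	NP
accD	227	A65	A	0	NP
accD	227	A67	A	0	NP
accD	227	A68	A	0	NP
accD	227	A69	G	0	1
accD	250	A64	G	1	NP
accD	250	A65	G	0	NP
accD	250	A67	G	0	NP
accD	250	A68	C	0	1
accD	250	A69	C	0	1
accD	251	A64	T	1	NP
accD	251	A65	T	0	NP
accD	251	A67	T	0	NP
accD	251	A68	C	0	1
accD	251	A69	C	0	1
accD	260	A64	A	1	NP
accD	260	A65	G	0	1
accD	260	A67	G	0	1
accD	260	A68	G	0	1
accD	260	A69	G	0	1
accD	266	A64	C	1	NP
accD	266	A65	T	0	0
accD	266	A67	C	0	NP
accD	266	A68	T	0	0
accD	266	A69	T	0	0
accD	283	A64	C	1	NP
accD	283	A65	G	0	1
accD	283	A67	C	0	NP
accD	283	A68	C	0	NP
accD	283	A69	C	0	NP
accD	305	A64	T	1	NP
accD	305	A65	C	0	1
accD	305	A67	T	0	NP
accD	305	A68	T	0	NP
accD	305	A69	T	0	NP
accD	339	A64	C	1	NP
accD	339	A65	A	0	1
accD	339	A67	C	0	NP
accD	339	A68	C	0	NP
accD	339	A69	C	0	NP
accD	345	A64	A	1	NP
accD	345	A65	C	0	1
accD	345	A67	A	0	NP
accD	345	A68	A	0	NP
accD	345	A69	A	0	NP
accD	346	A64	A	1	NP
accD	346	A65	G	0	1
accD	346	A67	G	0	1
accD	346	A68	G	0	1
accD	346	A69	G	0	1
accD	354	A64	C	1	NP
accD	354	A65	A	0	0
accD	354	A67	C	0	NP
accD	354	A68	C	0	NP
accD	354	A69	T	0	0
accD	365	A64	C	1	NP
accD	365	A65	A	0	0
accD	365	A67	T	0	0
accD	365	A68	G	0	0
accD	365	A69	G	0	0
accD	368	A64	T	1	NP
accD	368	A65	T	0	NP
accD	368	A67	T	0	NP
accD	368	A68	C	0	0
accD	368	A69	C	0	0
accD	372	A64	G	1	NP
accD	372	A65	G	0	NP
accD	372	A67	G	0	NP
accD	372	A68	A	0	1
accD	372	A69	A	0	1
accD	380	A64	G	1	NP
accD	380	A65	T	0	0
accD	380	A67	T	0	0
accD	380	A68	T	0	0
accD	380	A69	T	0	0
accD	388	A64	C	1	NP
accD	388	A65	T	0	1
accD	388	A67	C	0	NP
accD	388	A68	A	0	1
accD	388	A69	A	0	1
accD	389	A64	T	1	NP
accD	389	A65	G	0	1
accD	389	A67	G	0	1
accD	389	A68	G	0	1
accD	389	A69	G	0	1
accD	395	A64	A	1	NP
accD	395	A65	A	0	NP
accD	395	A67	A	0	NP
accD	395	A68	G	0	0
accD	395	A69	G	0	0
accD	408	A64	G	1	NP
accD	408	A65	G	0	NP
accD	408	A67	G	0	NP
accD	408	A68	A	0	0
accD	408	A69	A	0	0
accD	416	A64	A	1	NP
accD	416	A65	C	0	1
accD	416	A67	A	0	NP
accD	416	A68	A	0	NP
accD	416	A69	A	0	NP
accD	449	A64	C	1	NP
accD	449	A65	C	0	NP
accD	449	A67	C	0	NP
accD	449	A68	T	0	0
accD	449	A69	T	0	0
accD	450	A64	C	1	NP
accD	450	A65	A	0	0
accD	450	A67	C	0	NP
accD	450	A68	C	0	NP
accD	450	A69	C	0	NP
accD	468	A64	C	1	NP
accD	468	A65	A	0	1
accD	468	A67	A	0	1
accD	468	A68	C	0	NP
accD	468	A69	C	0	NP
accD	469	A64	G	1	NP
accD	469	A65	A	0	1
accD	469	A67	A	0	1
accD	469	A68	A	0	1
accD	469	A69	A	0	1
accD	470	A64	G	1	NP
accD	470	A65	T	0	1
accD	470	A67	G	0	NP
accD	470	A68	G	0	NP
accD	470	A69	G	0	NP
accD	474	A64	A	1	NP
accD	474	A65	C	0	1
accD	474	A67	T	0	1
accD	474	A68	A	0	NP
accD	474	A69	A	0	NP
accD	522	A64	A	1	NP
accD	522	A65	G	0	0
accD	522	A67	A	0	NP
accD	522	A68	A	0	NP
accD	522	A69	A	0	NP
accD	543	A64	T	1	NP
accD	543	A65	C	0	1
accD	543	A67	C	0	1
accD	543	A68	T	0	NP
accD	543	A69	T	0	NP
accD	704	A64	A	1	NP
accD	704	A65	G	0	1
accD	704	A67	G	0	1
accD	704	A68	G	0	1
accD	704	A69	G	0	1
accD	707	A64	G	1	NP
accD	707	A65	G	0	NP
accD	707	A67	C	0	0
accD	707	A68	G	0	NP
accD	707	A69	G	0	NP
accD	713	A64	T	1	NP
accD	713	A65	T	0	NP
accD	713	A67	T	0	NP
accD	713	A68	A	0	1
accD	713	A69	A	0	1
accD	746	A64	C	1	NP
accD	746	A65	C	0	NP
accD	746	A67	T	0	0
accD	746	A68	C	0	NP
accD	746	A69	C	0	NP
accD	755	A64	T	1	NP
accD	755	A65	T	0	NP
accD	755	A67	T	0	NP
accD	755	A68	T	0	NP
accD	755	A69	C	0	1
accD	781	A64	G	1	NP
accD	781	A65	T	0	1
accD	781	A67	G	0	NP
accD	781	A68	G	0	NP
accD	781	A69	G	0	NP
atp6	134	A24	G	1	NP
atp6	134	A67	T	0	1
atp6	134	A76	T	0	1
atp6	134	A83	G	0	NP
atp6	134	A90	G	0	NP
atp6	240	A24	G	1	NP
atp6	240	A67	C	0	1
atp6	240	A76	C	0	1
atp6	240	A83	C	0	1
atp6	240	A90	G	0	NP
atp6	296	A24	T	1	NP
atp6	296	A67	T	0	NP
atp6	296	A76	T	0	NP
atp6	296	A83	C	0	1
atp6	296	A90	T	0	NP
atp6	305	A24	T	1	NP
atp6	305	A67	C	0	1
atp6	305	A76	C	0	1
atp6	305	A83	T	0	NP
atp6	305	A90	T	0	NP
atp6	314	A24	T	1	NP
atp6	314	A67	G	0	1
atp6	314	A76	G	0	1
atp6	314	A83	G	0	1
atp6	314	A90	T	0	NP
atp6	338	A24	A	1	NP
atp6	338	A67	A	0	NP
atp6	338	A76	A	0	NP
atp6	338	A83	A	0	NP
atp6	338	A90	G	0	1
atp6	351	A24	C	1	NP
atp6	351	A67	G	0	1
atp6	351	A76	G	0	1
atp6	351	A83	G	0	1
atp6	351	A90	C	0	NP
atp6	512	A24	T	1	NP
atp6	512	A67	T	0	NP
atp6	512	A76	T	0	NP
atp6	512	A83	T	0	NP
atp6	512	A90	C	0	1
atp6	533	A24	T	1	NP
atp6	533	A67	T	0	NP
atp6	533	A76	T	0	NP
atp6	533	A83	T	0	NP
atp6	533	A90	C	0	1
atp6	625	A24	T	1	NP
atp6	625	A67	C	0	1
atp6	625	A76	C	0	1
atp6	625	A83	C	0	1
atp6	625	A90	C	0	1
atp6	637	A24	G	1	NP
atp6	637	A67	G	0	NP
atp6	637	A76	G	0	NP
atp6	637	A83	G	0	NP
atp6	637	A90	A	0	1
atp6	647	A24	A	1	NP
atp6	647	A67	A	0	NP
atp6	647	A76	A	0	NP
atp6	647	A83	A	0	NP
atp6	647	A90	T	0	1
atp6	653	A24	C	1	NP
atp6	653	A67	A	0	1
atp6	653	A76	A	0	1
atp6	653	A83	A	0	1
atp6	653	A90	C	0	NP
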