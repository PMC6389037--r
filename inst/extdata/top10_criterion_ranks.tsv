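gene	rank1	rank2	rank3	rank4	rank5	rank6	rank7	rank8	rank9	rank10
IL10	44	140	6	14	26	9	1	1	1	1
TLR4	11	92	17	43	92	29	1	1	1	1
CAT	59	78	11	31	71	37	1	1	1	1
NFKB1	3	26	13	5	16	8	1	205	205	1
AKT1	9	64	4	20	20	18	1	205	205	1
ADRB2	78	82	28	166	92	155	1	1	1	1
ICAM1	26	86	11	30	3	44	1	205	205	1
CST3	112	105	25	117	92	117	1	205	1	1
POMC	93	85	23	59	53	51	1	205	205	1
SPP1	25	45	26	44	30	5	1	205	205	205
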