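variable	level	overall	high_risk	low_risk
gender	female	186	76	110
gender	male	344	144	200
grade	G1	14	3	11
grade	G2	227	70	157
grade	G3	206	93	113
grade	G4	75	53	22
grade	GX	5	1	4
grade	unknown	3	0	3
stage	I	265	76	189
stage	II	57	25	32
stage	III	123	61	62
stage	IV	82	55	27
stage	unknown	3	3	0
t_stage	T1	21	8	13
t_stage	T1a	140	35	105
t_stage	T1b	110	35	75
t_stage	T2	55	22	33
t_stage	T2a	10	5	5
t_stage	T2b	4	4	0
t_stage	T3	5	2	3
t_stage	T3a	120	71	49
t_stage	T3b	52	27	25
t_stage	T3c	2	2	0
t_stage	T4	11	9	2
m_stage	M0	420	152	268
m_stage	M1	78	52	26
m_stage	MX	30	16	14
m_stage	unknown	2	0	2
n_stage	N0	239	107	132
n_stage	N1	16	12	4
n_stage	NX	275	101	174
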