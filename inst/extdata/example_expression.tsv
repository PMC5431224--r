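probe_id	c1	c2	m1	m2	c3	c4	m3	m4
P00001	100	110	420	380	95	105	400	410
P00002	200	190	48	52	210	205	55	50
P00003	150	160	155	150	145	155	150	160
P00004	80	85	82	88	90	84	86	83
P00005	300	290	310	295	305	300	290	310
P00006	50	55	52	48	54	51	49	53
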