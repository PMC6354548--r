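comparison	test	ref	region	tp	fp	fn	tn
AS-RR1	AS	RR1	brain_tissue	45	12	15	20
AS-RR2	AS	RR2	brain_tissue	32	25	4	31
AS-RR3	AS	RR3	brain_tissue	45	12	15	20
AS-RR1	AS	RR1	ventricle	5	30	0	57
AS-RR2	AS	RR2	ventricle	5	30	0	57
AS-RR3	AS	RR3	ventricle	3	32	0	57
AS-RR1	AS	RR1	structurewise	23	94	98	1901
AS-RR2	AS	RR2	structurewise	31	86	90	1909
AS-RR3	AS	RR3	structurewise	34	85	83	1914
AS-RRm	AS	RRm	structurewise	28	89	56	1943
RR1-RR2	RR1	RR2	structurewise	39	82	82	1913
RR1-RR3	RR1	RR3	structurewise	36	85	83	1912
RR2-RR3	RR2	RR3	structurewise	42	79	76	1919
RR1-RRm	RR1	RRm	structurewise	59	64	25	1968
RR2-RRm	RR2	RRm	structurewise	64	58	20	1974
RR3-RRm	RR3	RRm	structurewise	61	58	23	1974
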