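chromosome	full_markers	full_dart	full_ssr	full_cm	full_gap_cm	fw_markers	fw_dart	fw_ssr	fw_cm	fw_gap_cm	f2g_markers	physical_mbp	kbp_per_cm
1	207	191	16	167.8	0.8	80	72	8	114.0	1.4	62	40.7	357.3
2	244	219	25	129	0.5	131	112	19	122.1	0.9	98	63.8	522.1
3	270	256	14	102.4	0.4	128	115	13	124.6	1.0	102	79.7	639.2
4	106	93	13	86.6	0.8	57	44	13	76.1	1.3	52	41.1	539.9
5	189	166	23	130.7	0.7	74	54	20	100.3	1.4	68	73.8	736.1
6	271	231	40	116.5	0.4	104	72	32	121.6	1.2	88	50.3	413.7
7	224	210	14	117.3	0.5	75	64	11	130.5	1.7	68	51.9	548.4
8	275	262	13	118.6	0.4	107	95	12	116.2	1.1	94	68.4	588.9
9	220	204	16	118.3	0.5	78	64	14	92.5	1.2	66	38.4	415.1
10	263	246	17	117.4	0.4	92	82	10	87.4	1.0	82	38.6	441.4
11	215	196	19	99.5	0.5	103	87	16	91.5	0.9	89	40.8	445.4
Total	2484	2274	210	1303.9	0.5	1029	864	168	1176.8	1.1	869	587.5	NA
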