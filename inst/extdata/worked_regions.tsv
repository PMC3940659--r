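protein_id	kind	start	end
DP00016	LCR	81	96
DP00039	LCR	2	19
DP00039	LCR	29	65
DP00040	LCR	2	9
DP00040	LCR	23	34
DP00040	LCR	54	68
DP00040	LCR	71	106
DP00069	LCR	3	24
DP00069	LCR	97	112
DP00069	AR	101	116
DP00070	LCR	10	23
DP00070	LCR	63	78
DP00070	AR	35	40
DP00126	LCR	129	153
DP00126	LCR	172	223
DP00126	AR	274	279
DP00174	AR	19	23
DP00199	LCR	3	15
DP00199	LCR	17	31
DP00199	LCR	41	53
DP00199	LCR	82	96
DP00199	LCR	139	159
DP00199	LCR	196	205
DP00214	LCR	81	131
DP00214	LCR	272	282
DP00219	LCR	10	22
DP00219	LCR	72	83
DP00219	LCR	105	125
DP00287	LCR	10	57
DP00287	AR	72	76
DP00287	AR	147	158
DP00332	LCR	62	106
DP00332	LCR	145	173
DP00332	LCR	207	234
DP00332	LCR	252	267
DP00332	LCR	302	314
DP00332	AR	310	317
DP00372	AR	7	12
DP00372	AR	35	40
DP00372	AR	66	71
DP00521	AR	2	7
DP00521	LCR	163	173
DP00546	LCR	16	34
DP00546	LCR	116	133
DP00546	AR	167	175
DP00555	AR	35	40
DP00555	AR	73	78
DP00555	LCR	96	133
DP00592	AR	42	47
DP00617	LCR	12	22
DP00617	LCR	38	51
DP00630	LCR	65	82
DP00630	LCR	106	125
Abeta42	AR	16	21
Abeta42	AR	37	42
P01308	LCR	2	24
P01308	AR	36	42
P01308	AR	99	110
P02647	AR	8	15
P06654	LCR	69	114
P06654	LCR	241	253
P06654	LCR	379	413
P06654	LCR	427	442
P27986	LCR	79	102
P27986	LCR	303	314
P27986	LCR	533	548
P27986	AR	72	78
P27986	AR	263	269
P27986	AR	290	296
P27986	AR	331	336
P27986	AR	401	406
P27986	AR	483	495
P10636	AR	274	279
P01034	LCR	2	33
P01034	AR	10	20
P01034	AR	56	61
P01034	AR	84	92
P01034	AR	124	130
P04156	LCR	50	94
P04156	LCR	113	135
P04156	LCR	188	201
P04156	LCR	237	252
P04156	AR	8	17
P04156	AR	171	176
P04156	AR	178	185
P04156	AR	222	227
P04156	AR	231	235
P04156	AR	240	253
P05453	LCR	5	64
P05453	LCR	68	113
P05453	LCR	130	142
P05453	LCR	164	209
P05453	LCR	241	253
P05453	LCR	398	410
P05453	AR	9	18
P05453	AR	31	36
P05453	AR	45	56
P05453	AR	69	74
P05453	AR	102	108
P05453	AR	260	266
P05453	AR	278	285
P05453	AR	304	313
P05453	AR	426	445
P05453	AR	471	476
P05453	AR	527	538
P05453	AR	566	571
P05453	AR	584	596
P37840	LCR	10	23
P37840	LCR	63	78
P37840	AR	35	40
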