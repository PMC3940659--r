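protein_id	metric	digits	printed
DP00016	lcr_pct	0	10
DP00016	ar_pct	0	0
DP00039	lcr_pct	0	62
DP00039	ar_pct	0	0
DP00040	lcr_pct	0	66
DP00040	ar_pct	0	0
DP00069	lcr_pct	0	33
DP00069	ar_pct	0	14
DP00070	lcr_pct	0	21
DP00070	ar_pct	0	4
DP00126	lcr_pct	0	17
DP00126	ar_pct	0	1
DP00174	lcr_pct	0	0
DP00174	ar_pct	0	3
DP00199	lcr_pct	0	38
DP00199	ar_pct	0	0
DP00214	lcr_pct	0	20
DP00214	ar_pct	0	0
DP00219	lcr_pct	0	37
DP00219	ar_pct	0	0
DP00287	lcr_pct	0	23
DP00287	ar_pct	0	8
DP00332	lcr_pct	0	41
DP00332	ar_pct	0	3
DP00372	lcr_pct	0	0
DP00372	ar_pct	0	17
DP00521	lcr_pct	0	5
DP00521	ar_pct	0	3
DP00546	lcr_pct	0	21
DP00546	ar_pct	0	5
DP00555	lcr_pct	0	28
DP00592	lcr_pct	0	0
DP00592	ar_pct	0	10
DP00617	lcr_pct	0	36
DP00617	ar_pct	0	0
DP00630	lcr_pct	0	30
DP00630	ar_pct	0	0
Abeta42	lcr_pct	0	0
Abeta42	ar_pct	0	29
P01308	lcr_pct	2	20.91
P02647	ar_pct	2	3.00
P06654	lcr_pct	2	24.55
P27986	lcr_pct	2	7.18
P10636	ar_pct	2	1.36
P01034	lcr_pct	2	21.92
P01034	ar_pct	2	22.60
P04156	lcr_pct	2	38.74
P05453	lcr_pct	2	27.88
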