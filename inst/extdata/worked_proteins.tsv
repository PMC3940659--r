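protein_id	length	set
DP00016	164	disprot
DP00039	89	disprot
DP00040	107	disprot
DP00069	116	disprot
DP00070	140	disprot
DP00126	441	disprot
DP00174	149	disprot
DP00199	226	disprot
DP00214	314	disprot
DP00219	126	disprot
DP00287	213	disprot
DP00332	317	disprot
DP00372	106	disprot
DP00521	202	disprot
DP00546	175	disprot
DP00555	134	disprot
DP00592	62	disprot
DP00617	70	disprot
DP00630	127	disprot
Abeta42	42	disprot
P01308	110	amyloid_panel
P02647	267	amyloid_panel
P06654	448	amyloid_panel
P27986	724	amyloid_panel
P10636	441	amyloid_panel
P01034	146	amyloid_panel
P04156	253	amyloid_panel
P05453	685	amyloid_panel
P37840	140	amyloid_panel
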