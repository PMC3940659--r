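protein_id	ar_start	ar_end	lcr_start	lcr_end	overlap_start	overlap_end	overlap_length
DP00069	101	116	97	112	101	112	12
DP00332	310	317	302	314	310	314	5
P01034	10	20	2	33	10	20	11
P04156	240	253	237	252	240	252	13
P05453	9	18	5	64	9	18	10
P05453	31	36	5	64	31	36	6
P05453	45	56	5	64	45	56	12
P05453	69	74	68	113	69	74	6
P05453	102	108	68	113	102	108	7
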