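eye_id	group	observed_stripes	p	diameter1_mm	diameter2_mm	diameter3_mm
eye01	WT	11	0.39	3.03	2.94	3.35
eye02	WT	9	0.419	3.11	3.35	3.32
eye03	WT	12	0.436	2.93	3.05	3.12
eye04	mutant	5	0.59	3.19	3.39	3.31
eye05	mutant	6	0.588	3.01	3.26	2.95
eye06	mutant	4	0.371	3.26	3.2	3.24
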