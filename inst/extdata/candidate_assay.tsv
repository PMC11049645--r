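label	sequence	mass_da	retention_time	identification_score	ic50_um	ic50_sd	source
P1	PLPP	422.25	13.884	8.0791	ND	NA	whey
P2	VPPF	458.25	50.601	44.845	1573.85	256.05	both
P3	LPPL	438.28	27.735	8.7137	2558.90	5.70	both
P4	YPF	425.19	24.940	55.918	368.54	12.97	both
P5	PALF	446.25	38.521	9.4209	1746.7	29.90	whey
P6	FVY	427.21	21.367	43.876	ND	NA	both
P7	LYL	407.24	28.303	36.833	ND	NA	whey
P8	LLPL	454.31	35.932	38.717	ND	NA	both
P9	LLLP	454.31	32.377	28.962	213.99	0.64	both
P11	LVW	416.24	30.462	55.918	ND	NA	whey
P12	LWV	416.24	29.518	36.05	ND	NA	both
P14	LLW	430.26	36.161	48.874	ND	NA	both
P19	IPI	341.23	NA	NA	9.28	0.52	NA
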