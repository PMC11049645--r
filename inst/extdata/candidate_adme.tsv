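label	sequence	solubility_esol	solubility_ali	solubility_silicos_it	gi_absorption	bbb_permeant	pgp_substrate	cyp1a2	cyp2c19	cyp2c9	cyp2d6	cyp3a4
P1	PLPP	VS	VS	S	High	No	Yes	No	No	No	No	No
P2	VPPF	VS	VS	S	High	No	Yes	No	No	No	No	No
P3	LPPL	VS	VS	S	High	No	Yes	No	No	No	No	No
P4	YPF	VS	VS	MS	High	No	Yes	No	No	No	No	No
P5	PALF	VS	VS	MS	High	No	Yes	No	No	No	No	No
P6	FVY	VS	VS	MS	High	No	Yes	No	No	No	No	No
P7	LYL	VS	VS	S	High	No	Yes	No	No	No	No	No
P8	LLPL	VS	VS	S	High	No	Yes	No	No	No	No	No
P9	LLLP	VS	VS	S	High	No	Yes	No	No	No	No	No
P10	WVL	VS	VS	MS	High	No	Yes	No	No	No	No	No
P11	LVW	VS	VS	MS	High	No	Yes	No	No	No	No	No
P12	LWV	VS	VS	MS	High	No	Yes	No	No	No	No	No
P13	FWV	S	S	PS	High	No	Yes	No	No	No	Yes	No
P14	LLW	VS	S	MS	High	No	Yes	No	No	No	No	No
P15	LFF	VS	VS	PS	High	No	Yes	No	No	No	Yes	Yes
P16	FLF	VS	VS	PS	High	No	Yes	No	No	No	Yes	Yes
P17	LWF	S	S	PS	High	No	Yes	No	No	No	Yes	No
P18	LFW	S	S	PS	High	No	Yes	No	No	No	Yes	No
P19	IPI	VS	VS	S	High	No	Yes	No	No	No	No	No
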