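name	cut_after	blocked_p1prime	note
proteinase_k	AFILTVWY		Broad serine protease; cleaves C-terminal to aliphatic and aromatic residues.
papain	RK	P	Cysteine protease; basic-P1 core rule, Pro at P1' blocks; P2-hydrophobic refinement not modelled.
thermolysin	AFILMV	P	P1'-hydrophobic specificity approximated as a P1 rule within the cut-after grammar; Pro blocks.
bromelain	AGKRY	P	Stem bromelain; broad preference approximated; Pro at P1' blocks.
subtilisin	AFLMWY		Broad specificity for large uncharged P1 residues (approximation).
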