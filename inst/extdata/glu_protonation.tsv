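residue	state	atom	shift_ppm
E	deprotonated	CG	36.1
E	deprotonated	CD	183.8
E	protonated	CG	32.7
E	protonated	CD	179.7
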