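residue	isomer	atom	shift_ppm
P	trans	CB	32.0
P	trans	CG	27.5
P	cis	CB	34.2
P	cis	CG	24.6
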