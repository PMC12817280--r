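residue	atom	context	correction_ppm
G	CA	prePro	-0.77
G	CA	none	0
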