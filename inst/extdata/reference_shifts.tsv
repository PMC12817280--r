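residue	atom	class	mean_ppm	sd_ppm
A	CA	helix	54.87	0.92
A	CA	sheet	50.93	1.12
A	CA	coil	52.57	0.98
A	CB	helix	18.33	0.89
A	CB	sheet	21.41	1.40
A	CB	coil	19.16	1.09
G	CA	helix	46.86	0.95
G	CA	sheet	44.87	1.16
G	CA	coil	45.36	0.88
S	CA	helix	61.33	0.99
S	CA	sheet	57.40	1.18
S	CA	coil	58.32	1.08
S	CB	helix	62.84	0.82
S	CB	sheet	65.26	1.37
S	CB	coil	63.85	0.93
P	CA	helix	65.50	0.88
P	CA	sheet	62.75	1.07
P	CA	coil	63.26	0.93
P	CB	helix	31.57	0.75
P	CB	sheet	32.28	1.09
P	CB	coil	31.87	0.81
Y	CA	helix	60.84	1.27
Y	CA	sheet	56.75	1.35
Y	CA	coil	57.74	1.22
Y	CB	helix	38.27	1.03
Y	CB	sheet	40.96	1.52
Y	CB	coil	38.83	1.17
E	CA	helix	59.01	0.92
E	CA	sheet	55.13	1.12
E	CA	coil	56.67	1.04
E	CB	helix	29.29	0.89
E	CB	sheet	31.90	1.49
E	CB	coil	30.10	0.99
N	CA	helix	55.49	0.93
N	CA	sheet	52.23	1.14
N	CA	coil	53.00	1.01
N	CB	helix	38.24	0.98
N	CB	sheet	39.57	1.45
N	CB	coil	38.70	1.10
Q	CA	helix	58.58	0.93
Q	CA	sheet	54.70	1.16
Q	CA	coil	55.90	1.00
Q	CB	helix	28.78	0.87
Q	CB	sheet	31.51	1.48
Q	CB	coil	29.32	0.98
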