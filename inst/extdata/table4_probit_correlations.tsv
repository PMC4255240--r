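AREA	V1	V2	V4	TEO	TEpd	MT	DP	8L	8m	STPc	7A
V1	1	0.85	0.81	0.75	0.47	0.35	0.44	0.5	-0.17	0.11	0.49
V2	0.85	1	0.87	0.83	0.52	0.55	0.65	0.39	-0.05	0.36	0.58
V4	0.81	0.87	1	0.96	0.89	0.88	0.72	0.46	-0.17	0.52	0.37
TEO	0.75	0.83	0.96	1	0.84	0.77	0.82	0.58	-0.4	0.51	0.52
TEpd	0.47	0.52	0.89	0.84	1	0.82	0.71	0.65	-0.34	0.51	0.73
MT	0.35	0.55	0.88	0.77	0.82	1	0.81	0.44	0.08	0.57	0.23
DP	0.44	0.65	0.72	0.82	0.71	0.81	1	0.54	-0.38	0.13	0.35
8L	0.5	0.39	0.46	0.58	0.65	0.44	0.54	1	-0.11	-0.11	0.23
8m	-0.17	-0.05	-0.17	-0.4	-0.34	0.08	-0.38	-0.11	1	0.63	-0.28
STPc	0.11	0.36	0.52	0.51	0.51	0.57	0.13	-0.11	0.63	1	0.42
7A	0.49	0.58	0.37	0.52	0.73	0.23	0.35	0.23	-0.28	0.42	1
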