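AREA	V1	V2	V4	TEO	TEpd	MT	DP	8L	8m	STPc	7A
V1	1	0.76	0.82	0.72	0.39	0.45	0.51	0.5	0.42	-0.15	0.47
V2	0.76	1	0.9	0.86	0.4	0.59	0.63	0.37	0.51	0.15	-0.1
V4	0.82	0.9	1	0.92	0.48	0.59	0.68	0.5	0.19	-0.1	-0.06
TEO	0.72	0.86	0.92	1	0.58	0.69	0.82	0.73	0.31	0.19	0.25
TEpd	0.39	0.4	0.48	0.58	1	0.72	0.64	0.51	0.36	0.57	0.3
MT	0.45	0.59	0.59	0.69	0.72	1	0.9	0.51	0.25	0.58	-0.03
DP	0.51	0.63	0.68	0.82	0.64	0.9	1	0.57	0.04	0.33	0.21
8L	0.5	0.37	0.5	0.73	0.51	0.51	0.57	1	0.12	0.04	-0.09
8m	0.42	0.51	0.19	0.31	0.36	0.25	0.04	0.12	1	0.34	0.45
STPc	-0.15	0.15	-0.1	0.19	0.57	0.58	0.33	0.04	0.34	1	0.28
7A	0.47	-0.1	-0.06	0.25	0.3	-0.03	0.21	-0.09	0.45	0.28	1
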