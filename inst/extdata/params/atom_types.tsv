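# rnarefine parameter file v1
# type	sigma	epsilon	charge	element	gb_radius	gb_screen
C	3.3997	0.0860	0.0000	C	1.70	0.72
CA	3.3997	0.0860	0.0000	C	1.70	0.72
CB	3.3997	0.0860	0.0000	C	1.70	0.72
CK	3.3997	0.0860	0.0000	C	1.70	0.72
CM	3.3997	0.0860	0.0000	C	1.70	0.72
CQ	3.3997	0.0860	0.0000	C	1.70	0.72
CT	3.3997	0.1094	0.0000	C	1.70	0.72
H	1.0691	0.0157	0.0000	H	1.30	0.85
H1	2.4714	0.0157	0.0000	H	1.20	0.85
H2	2.2932	0.0157	0.0000	H	1.20	0.85
H4	2.5106	0.0150	0.0000	H	1.20	0.85
H5	2.4215	0.0150	0.0000	H	1.20	0.85
HA	2.5996	0.0150	0.0000	H	1.20	0.85
HC	2.6495	0.0157	0.0000	H	1.20	0.85
HO	0.5345	0.0001	0.0000	H	0.80	0.85
N*	3.2500	0.1700	0.0000	N	1.55	0.79
N2	3.2500	0.1700	0.0000	N	1.55	0.79
NA	3.2500	0.1700	0.0000	N	1.55	0.79
NB	3.2500	0.1700	0.0000	N	1.55	0.79
NC	3.2500	0.1700	0.0000	N	1.55	0.79
O	2.9599	0.2100	0.0000	O	1.50	0.85
O2	2.9599	0.2100	0.0000	O	1.50	0.85
OH	3.0665	0.2104	0.0000	O	1.50	0.85
OS	3.0000	0.1700	0.0000	O	1.50	0.85
P	3.7418	0.2000	0.0000	P	1.85	0.86
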