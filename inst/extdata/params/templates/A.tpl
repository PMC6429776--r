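# rnarefine residue template v1
residue A
aliases RA ADE
class A
kind ribo
formal_charge -1
atoms
P	P	P	1.1662	2.6449	0.8860	-4.6182	-
OP1	O2	O	-0.7760	3.9767	1.3070	-4.1323	-
OP2	O2	O	-0.7760	1.9727	1.6542	-5.8624	-
O5'	OS	O	-0.4954	1.6098	0.8537	-3.3856	-
C5'	CT	C	0.0558	0.2281	0.5639	-3.5962	-
C4'	CT	C	0.1065	-0.5028	0.5524	-2.2527	-
O4'	OS	O	-0.3548	-0.0048	-0.4808	-1.3679	-
C3'	CT	C	0.2022	-0.2632	1.8644	-1.4832	-
O3'	OS	O	-0.5246	-1.1419	2.8964	-1.9340	-
C2'	CT	C	0.0670	-0.5409	1.4460	-0.0279	-
O2'	OH	O	-0.6139	-1.9415	1.4782	0.2537	-
C1'	CT	C	0.0394	0.0000	0.0000	0.0000	-
N9	N*	N	-0.0259	1.3747	-0.0183	0.5036	-
C8	CK	C	0.2003	2.5099	-0.0024	-0.2504	-
N7	NB	N	-0.6076	3.5569	-0.0250	0.5217	-
C5	CB	C	0.0512	3.1622	-0.0507	1.8167	-
C6	CA	C	0.7006	3.8290	-0.0908	3.0530	-
N6	N2	N	-0.9022	5.2117	-0.0969	3.1112	-
N1	NC	N	-0.7618	3.1022	-0.1163	4.1645	-
C2	CQ	C	0.5872	1.7830	-0.1107	4.1174	-
N3	NC	N	-0.7000	1.1154	-0.0799	2.9838	-
C4	CB	C	0.3050	1.7570	-0.0520	1.8209	-
H5'	H1	H	0.0679	0.1299	-0.4119	-4.0722	-
H5''	H1	H	0.0679	-0.2090	1.3274	-4.2401	-
H4'	H1	H	0.1174	-1.5718	0.4132	-2.4188	-
H3'	H1	H	0.0615	0.7739	2.1807	-1.5934	-
HO3'	HO	H	0.4376	-0.9383	3.6847	-1.4126	3'
H2'	H1	H	0.0972	0.0099	2.0771	0.6701	-
HO2'	HO	H	0.4186	-2.0314	1.6188	1.2064	-
H1'	H2	H	0.2007	-0.6369	-0.6273	0.6234	-
H8	H5	H	0.1553	2.5360	0.0251	-1.3298	-
H61	H	H	0.4115	5.6602	-0.1199	3.9704	-
H62	H	H	0.4115	5.7318	-0.0813	2.2928	-
H2	H5	H	0.0473	1.2306	-0.1330	5.0456	-
HO5'	HO	H	0.4295	2.0535	0.8572	-4.2369	5'
bonds
P	OP1
P	OP2
P	O5'
O5'	C5'
O5'	HO5'
C5'	C4'
C5'	H5'
C5'	H5''
C4'	O4'
C4'	C3'
C4'	H4'
O4'	C1'
C3'	O3'
C3'	C2'
C3'	H3'
O3'	HO3'
C2'	O2'
C2'	C1'
C2'	H2'
O2'	HO2'
C1'	N9
C1'	H1'
N9	C8
N9	C4
C8	N7
C8	H8
N7	C5
C5	C6
C5	C4
C6	N6
C6	N1
N6	H61
N6	H62
N1	C2
C2	N3
C2	H2
N3	C4
donors
N6	H61
N6	H62
acceptors
N1
N3
N7
wc_edge
N1
N6
H61
end
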