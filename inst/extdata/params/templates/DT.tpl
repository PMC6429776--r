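# rnarefine residue template v1
residue DT
aliases THY T
class T
kind deoxy
formal_charge -1
atoms
P	P	P	1.1662	-5.2096	-1.3117	-0.1975	-
OP1	O2	O	-0.7760	-5.4102	-2.5268	0.6602	-
OP2	O2	O	-0.7760	-6.2539	-0.0820	-0.0976	-
O5'	OS	O	-0.4954	-3.7750	-0.5822	-0.0249	-
C5'	CT	C	0.0558	-3.4144	0.0346	1.1996	-
C4'	CT	C	0.1065	-2.0007	0.5870	1.0752	-
O4'	OS	O	-0.3691	-1.0489	-0.4743	0.8599	-
C3'	CT	C	0.2022	-1.8034	1.5129	-0.1128	-
O3'	OS	O	-0.5246	-2.2490	2.8302	0.2017	-
C2'	CT	C	-0.0854	-0.3125	1.4486	-0.3423	-
C1'	CT	C	0.0680	0.0000	0.0000	0.0000	-
N1	N*	N	-0.0336	0.0730	-0.8425	-1.1582	-
C2	C	C	0.5584	1.2503	-0.9221	-1.9325	-
O2	O	O	-0.5974	2.2799	-0.2929	-1.6818	-
N3	NA	N	-0.4433	1.1784	-1.7824	-3.0329	-
C4	C	C	0.5101	0.0892	-2.5456	-3.4254	-
O4	O	O	-0.5656	0.0949	-3.2841	-4.4063	-
C5	CM	C	-0.0068	-1.1137	-2.4081	-2.5617	-
C7	CT	C	-0.2362	-2.3311	-3.1986	-2.9197	-
C6	CM	C	-0.2302	-1.0479	-1.5850	-1.5070	-
H5'	H1	H	0.0679	-4.1198	0.8409	1.4128	-
H5''	H1	H	0.0679	-3.4624	-0.7090	1.9991	-
H4'	H1	H	0.1174	-1.7312	1.0780	2.0154	-
H3'	H1	H	0.0615	-2.3724	1.1961	-0.9914	-
HO3'	HO	H	0.4376	-2.1021	3.3814	-0.5867	3'
H2'	HC	H	0.0718	-0.0899	1.6537	-1.3963	-
H2''	HC	H	0.0718	0.2653	2.1446	0.2739	-
H1'	H2	H	0.1804	0.9485	-0.0903	0.5404	-
H3	H	H	0.3420	2.0147	-1.8560	-3.6048	-
H71	HC	H	0.0770	-2.6732	-2.9153	-3.9137	-
H72	HC	H	0.0770	-3.1226	-3.0047	-2.1965	-
H73	HC	H	0.0770	-2.0951	-4.2623	-2.9078	-
H6	H4	H	0.2607	-1.9035	-1.4562	-0.8506	-
HO5'	HO	H	0.4295	-4.6664	-0.9283	0.0592	5'
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
C2'	C1'
C2'	H2'
C2'	H2''
C1'	N1
C1'	H1'
N1	C2
N1	C6
C2	O2
C2	N3
N3	C4
N3	H3
C4	O4
C4	C5
C5	C7
C5	C6
C7	H71
C7	H72
C7	H73
C6	H6
donors
N3	H3
acceptors
O2
O4
wc_edge
N3
H3
O4
end
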