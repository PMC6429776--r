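# rnarefine residue template v1
residue DU
class U
kind deoxy
formal_charge -1
atoms
P	P	P	1.1662	-5.3590	-0.4239	-0.0309	-
OP1	O2	O	-0.7760	-5.8066	-1.2205	1.1596	-
OP2	O2	O	-0.7760	-6.1583	0.9206	-0.4388	-
O5'	OS	O	-0.4954	-3.8190	0.0722	0.0179	-
C5'	CT	C	0.0558	-3.3407	0.8568	1.0975	-
C4'	CT	C	0.1065	-1.8557	1.1247	0.8914	-
O4'	OS	O	-0.3691	-1.1011	-0.1035	0.9172	-
C3'	CT	C	0.2022	-1.5220	1.7403	-0.4565	-
O3'	OS	O	-0.5246	-1.7328	3.1502	-0.4273	-
C2'	CT	C	-0.0854	-0.0673	1.3792	-0.6376	-
C1'	CT	C	0.0680	0.0000	0.0000	0.0000	-
N1	N*	N	0.0319	-0.0884	-1.0620	-0.9597	-
C2	C	C	0.4591	1.0473	-1.4972	-1.6779	-
O2	O	O	-0.5573	2.1729	-1.0115	-1.5425	-
N3	NA	N	-0.3645	0.8144	-2.5445	-2.5800	-
C4	C	C	0.5856	-0.3953	-3.1749	-2.8258	-
O4	O	O	-0.5857	-0.5522	-4.0897	-3.6280	-
C5	CM	C	-0.3731	-1.5299	-2.6592	-2.0337	-
C6	CM	C	-0.1222	-1.3235	-1.6620	-1.1695	-
H5'	H1	H	0.0679	-3.8957	1.7971	1.1268	-
H5''	H1	H	0.0679	-3.5022	0.3120	2.0310	-
H4'	H1	H	0.1174	-1.4928	1.7452	1.7167	-
H3'	H1	H	0.0615	-2.1496	1.3511	-1.2631	-
HO3'	HO	H	0.4376	-1.5064	3.4950	-1.3086	3'
H2'	HC	H	0.0718	0.1711	1.3231	-1.7066	-
H2''	HC	H	0.0718	0.6295	2.0787	-0.1652	-
H1'	H2	H	0.1804	0.9274	-0.1367	0.5666	-
H3	H	H	0.3154	1.6161	-2.8755	-3.1093	-
H5	HA	H	0.1811	-2.5082	-3.1034	-2.1719	-
H6	H4	H	0.2188	-2.1428	-1.2686	-0.5775	-
HO5'	HO	H	0.4295	-4.7549	-0.0935	0.1529	5'
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
C5	C6
C5	H5
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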