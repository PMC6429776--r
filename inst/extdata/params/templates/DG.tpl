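# rnarefine residue template v1
residue DG
class G
kind deoxy
formal_charge -1
atoms
P	P	P	1.1662	-2.8973	1.1699	4.3931	-
OP1	O2	O	-0.7760	-4.0146	2.0132	3.9145	-
OP2	O2	O	-0.7760	-2.1810	1.5175	5.7903	-
O5'	OS	O	-0.4954	-1.7854	1.0438	3.2357	-
C5'	CT	C	0.0558	-0.4358	0.6984	3.5499	-
C4'	CT	C	0.1065	0.3802	0.6032	2.2594	-
O4'	OS	O	-0.3691	-0.1098	-0.4329	1.3701	-
C3'	CT	C	0.2022	0.2539	1.9027	1.4280	-
O3'	OS	O	-0.5246	1.1508	2.9098	1.9023	-
C2'	CT	C	-0.0854	0.6064	1.4139	0.0079	-
C1'	CT	C	0.0680	0.0000	0.0000	0.0000	-
N9	N*	N	0.0390	-1.3335	0.0279	-0.6035	-
C8	CK	C	0.1277	-2.5190	0.1195	0.0647	-
N7	NB	N	-0.5806	-3.5058	0.1189	-0.7841	-
C5	CB	C	0.1647	-3.0135	0.0271	-2.0435	-
C6	C	C	0.4673	-3.6001	-0.0160	-3.3300	-
O6	O	O	-0.5694	-4.8103	0.0326	-3.4660	-
N1	NA	N	-0.4884	-2.7851	-0.1052	-4.4034	-
C2	CA	C	0.7560	-1.4343	-0.1650	-4.2394	-
N2	N2	N	-0.9769	-0.6320	-0.2631	-5.3478	-
N3	NC	N	-0.6420	-0.8773	-0.1271	-3.0498	-
C4	CB	C	0.1125	-1.6185	-0.0308	-1.9403	-
H5'	H1	H	0.0679	-0.4174	-0.2623	4.0634	-
H5''	H1	H	0.0679	-0.0048	1.4638	4.1955	-
H4'	H1	H	0.1174	1.4269	0.4175	2.4987	-
H3'	H1	H	0.0615	-0.7716	2.2713	1.4569	-
HO3'	HO	H	0.4376	1.0190	3.6863	1.3421	3'
H2'	HC	H	0.0718	1.6863	1.3755	-0.1337	-
H2''	HC	H	0.0718	0.1347	2.0427	-0.7471	-
H1'	H2	H	0.1804	0.6470	-0.6796	-0.5556	-
H8	H5	H	0.1640	-2.6238	0.1827	1.1384	-
H1	H	H	0.3424	-3.1650	-0.1367	-5.2957	-
H21	H	H	0.4364	0.3318	-0.3024	-5.2471	-
H22	H	H	0.4364	-1.0286	-0.2972	-6.2326	-
HO5'	HO	H	0.4295	-2.2840	1.0996	4.0542	5'
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
C1'	N9
C1'	H1'
N9	C8
N9	C4
C8	N7
C8	H8
N7	C5
C5	C6
C5	C4
C6	O6
C6	N1
N1	C2
N1	H1
C2	N2
C2	N3
N2	H21
N2	H22
N3	C4
donors
N1	H1
N2	H21
N2	H22
acceptors
O6
N3
N7
wc_edge
O6
N1
H1
N2
H21
end
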