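# rnarefine residue template v1
residue DC
class C
kind deoxy
formal_charge -1
atoms
P	P	P	1.1662	3.4088	-0.2404	-4.1700	-
OP1	O2	O	-0.7760	4.4450	0.8006	-3.9913	-
OP2	O2	O	-0.7760	2.8264	-0.5385	-5.6398	-
O5'	OS	O	-0.4954	2.1899	0.0360	-3.1541	-
C5'	CT	C	0.0558	0.8408	-0.2291	-3.5384	-
C4'	CT	C	0.1065	-0.0933	0.0777	-2.3661	-
O4'	OS	O	-0.3691	0.1741	-0.7588	-1.2127	-
C3'	CT	C	0.2022	0.1274	1.5178	-1.8450	-
O3'	OS	O	-0.5246	-0.5829	2.4703	-2.6395	-
C2'	CT	C	-0.0854	-0.4123	1.4272	-0.4031	-
C1'	CT	C	0.0680	0.0000	0.0000	0.0000	-
N1	N*	N	-0.0629	1.2674	0.0318	0.7334	-
C2	C	C	0.7391	1.2690	0.2761	2.0554	-
O2	O	O	-0.6399	0.2110	0.4718	2.6309	-
N3	NC	N	-0.7731	2.4069	0.3091	2.7471	-
C4	CA	C	0.8038	3.5708	0.1009	2.1471	-
N4	N2	N	-0.9677	4.7399	0.1378	2.8712	-
C5	CM	C	-0.5362	3.6031	-0.1540	0.7611	-
C6	CM	C	-0.0094	2.4384	-0.1888	0.0728	-
H5'	H1	H	0.0679	0.7414	-1.2784	-3.8163	-
H5''	H1	H	0.0679	0.5733	0.3980	-4.3881	-
H4'	H1	H	0.1174	-1.1296	-0.0477	-2.6794	-
H3'	H1	H	0.0615	1.1903	1.7571	-1.8362	-
HO3'	HO	H	0.4376	-0.4008	3.3413	-2.2597	3'
H2'	HC	H	0.0718	-1.4958	1.5394	-0.3854	-
H2''	HC	H	0.0718	0.0674	2.1659	0.2398	-
H1'	H2	H	0.1804	-0.7771	-0.4528	0.6158	-
H41	H	H	0.4234	4.7139	0.3168	3.8240	-
H42	H	H	0.4234	5.5892	-0.0196	2.4300	-
H5	HA	H	0.1928	4.5434	-0.3262	0.2568	-
H6	H4	H	0.1958	2.4376	-0.3863	-0.9886	-
HO5'	HO	H	0.4295	2.7630	-0.1609	-3.8987	5'
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
C4	N4
C4	C5
N4	H41
N4	H42
C5	C6
C5	H5
C6	H6
donors
N4	H41
N4	H42
acceptors
O2
N3
wc_edge
N4
H41
N3
O2
end
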