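# rnarefine residue template v1
residue DA
class A
kind deoxy
formal_charge -1
atoms
P	P	P	1.1662	2.7217	0.1057	-4.6526	-
OP1	O2	O	-0.7760	3.9433	0.8982	-4.3895	-
OP2	O2	O	-0.7760	1.9493	0.2763	-6.0546	-
O5'	OS	O	-0.4954	1.6828	0.3023	-3.4393	-
C5'	CT	C	0.0558	0.2830	0.0945	-3.6314	-
C4'	CT	C	0.1065	-0.4511	0.3024	-2.3055	-
O4'	OS	O	-0.3691	-0.0349	-0.6445	-1.2879	-
C3'	CT	C	0.2022	-0.1113	1.6835	-1.6961	-
O3'	OS	O	-0.5246	-0.9062	2.7175	-2.2796	-
C2'	CT	C	-0.0854	-0.4268	1.4642	-0.2023	-
C1'	CT	C	0.0680	0.0000	0.0000	0.0000	-
N9	N*	N	-0.0336	1.3657	-0.0561	0.5288	-
C8	CK	C	0.1919	2.5052	-0.2205	-0.1986	-
N7	NB	N	-0.6160	3.5400	-0.2198	0.5903	-
C5	CB	C	0.0428	3.1316	-0.0498	1.8707	-
C6	CA	C	0.6922	3.7807	0.0217	3.1143	-
N6	N2	N	-0.9106	5.1584	-0.0773	3.2006	-
N1	NC	N	-0.7702	3.0417	0.1920	4.2059	-
C2	CQ	C	0.5788	1.7279	0.2866	4.1330	-
N3	NC	N	-0.7084	1.0761	0.2197	2.9918	-
C4	CB	C	0.2966	1.7300	0.0506	1.8468	-
H5'	H1	H	0.0679	0.1126	-0.9224	-3.9860	-
H5''	H1	H	0.0679	-0.0917	0.8032	-4.3688	-
H4'	H1	H	0.1174	-1.5260	0.2224	-2.4644	-
H3'	H1	H	0.0615	0.9474	1.9045	-1.8306	-
HO3'	HO	H	0.4376	-0.6438	3.5454	-1.8561	3'
H2'	HC	H	0.0718	-1.4907	1.5914	-0.0060	-
H2''	HC	H	0.0718	0.1677	2.1323	0.4224	-
H1'	H2	H	0.1804	-0.6862	-0.4971	0.6859	-
H8	H5	H	0.1553	2.5443	-0.3342	-1.2714	-
H61	H	H	0.4115	5.5957	-0.0219	4.0645	-
H62	H	H	0.4115	5.6867	-0.2049	2.3965	-
H2	H5	H	0.0473	1.1656	0.4236	5.0451	-
HO5'	HO	H	0.4295	2.1286	0.1684	-4.2788	5'
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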