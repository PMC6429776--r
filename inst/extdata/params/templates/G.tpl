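# rnarefine residue template v1
residue G
aliases RG GUA
class G
kind ribo
formal_charge -1
atoms
P	P	P	1.1662	-1.5847	2.0375	4.7371	-
OP1	O2	O	-0.7760	-2.9611	2.4590	4.3995	-
OP2	O2	O	-0.7760	-0.6503	3.0056	5.6210	-
O5'	OS	O	-0.4954	-0.8053	1.6209	3.3921	-
C5'	CT	C	0.0558	0.5115	1.0717	3.4478	-
C4'	CT	C	0.1065	0.9824	0.7255	2.0351	-
O4'	OS	O	-0.3548	0.1501	-0.2847	1.4139	-
C3'	CT	C	0.2022	0.8677	1.9433	1.1011	-
O3'	OS	O	-0.5246	1.9925	2.8134	1.2452	-
C2'	CT	C	0.0670	0.8033	1.2855	-0.2903	-
O2'	OH	O	-0.6139	2.1139	0.9777	-0.7691	-
C1'	CT	C	0.0394	0.0000	0.0000	0.0000	-
N9	N*	N	0.0473	-1.4195	0.2118	-0.2927	-
C8	CK	C	0.1352	-2.3821	0.5718	0.6050	-
N7	NB	N	-0.5731	-3.5313	0.6728	0.0030	-
C5	CB	C	0.1722	-3.3749	0.3845	-1.3125	-
C6	C	C	0.4748	-4.2524	0.3336	-2.4205	-
O6	O	O	-0.5619	-5.4383	0.5849	-2.2897	-
N1	NA	N	-0.4809	-3.7427	0.0059	-3.6276	-
C2	CA	C	0.7635	-2.4172	-0.2794	-3.7598	-
N2	N2	N	-0.9694	-1.9288	-0.6163	-4.9974	-
N3	NC	N	-0.6345	-1.5917	-0.2358	-2.7388	-
C4	CB	C	0.1200	-2.0231	0.0873	-1.5143	-
H5'	H1	H	0.0679	0.5027	0.1686	4.0597	-
H5''	H1	H	0.0679	1.1912	1.8011	3.8889	-
H4'	H1	H	0.1174	2.0171	0.3814	2.0667	-
H3'	H1	H	0.0615	-0.0545	2.4876	1.3044	-
HO3'	HO	H	0.4376	1.8563	3.5505	0.6351	3'
H2'	H1	H	0.0972	0.2714	1.9226	-0.9971	-
HO2'	HO	H	0.4186	2.0629	0.9667	-1.7356	-
H1'	H2	H	0.2007	0.3859	-0.8282	-0.5952	-
H8	H5	H	0.1640	-2.2161	0.7465	1.6577	-
H1	H	H	0.3424	-4.3253	-0.0353	-4.4025	-
H21	H	H	0.4364	-0.9859	-0.8170	-5.1088	-
H22	H	H	0.4364	-2.5264	-0.6557	-5.7602	-
HO5'	HO	H	0.4295	-1.0852	1.8323	4.2857	5'
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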