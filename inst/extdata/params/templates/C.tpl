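# rnarefine residue template v1
residue C
aliases RC CYT
class C
kind ribo
formal_charge -1
atoms
P	P	P	1.1662	3.7468	-0.0367	-3.8816	-
OP1	O2	O	-0.7760	4.5905	1.1751	-3.7967	-
OP2	O2	O	-0.7760	3.3209	-0.6102	-5.3244	-
O5'	OS	O	-0.4954	2.4320	0.1598	-2.9736	-
C5'	CT	C	0.0558	1.1439	-0.2208	-3.4566	-
C4'	CT	C	0.1065	0.0958	0.0315	-2.3720	-
O4'	OS	O	-0.3548	0.3340	-0.7663	-1.1858	-
C3'	CT	C	0.2022	0.1565	1.4875	-1.8736	-
O3'	OS	O	-0.5246	-0.5601	2.3622	-2.7475	-
C2'	CT	C	0.0670	-0.4894	1.3836	-0.4787	-
O2'	OH	O	-0.6139	-1.9145	1.4230	-0.5744	-
C1'	CT	C	0.0394	0.0000	0.0000	0.0000	-
N1	N*	N	-0.0524	1.2022	0.1455	0.8244	-
C2	C	C	0.7495	1.0844	0.4092	2.1370	-
O2	O	O	-0.6295	-0.0258	0.5263	2.6290	-
N3	NC	N	-0.7627	2.1604	0.5453	2.9110	-
C4	CA	C	0.8142	3.3793	0.4236	2.4022	-
N4	N2	N	-0.9573	4.4832	0.5664	3.2097	-
C5	CM	C	-0.5258	3.5367	0.1520	1.0277	-
C6	CM	C	0.0010	2.4333	0.0101	0.2565	-
H5'	H1	H	0.0679	1.1516	-1.2792	-3.7149	-
H5''	H1	H	0.0679	0.8989	0.3678	-4.3416	-
H4'	H1	H	0.1174	-0.8978	-0.1817	-2.7652	-
H3'	H1	H	0.0615	1.1939	1.8111	-1.7863	-
HO3'	HO	H	0.4376	-0.4811	3.2525	-2.3775	3'
H2'	H1	H	0.0972	-0.1235	2.1718	0.1782	-
HO2'	HO	H	0.4186	-2.2426	1.7622	0.2690	-
H1'	H2	H	0.2007	-0.7849	-0.5023	0.5651	-
H41	H	H	0.4234	4.3722	0.7570	4.1541	-
H42	H	H	0.4234	5.3730	0.4728	2.8366	-
H5	HA	H	0.1928	4.5227	0.0497	0.5993	-
H6	H4	H	0.1958	2.5284	-0.2010	-0.7984	-
HO5'	HO	H	0.4295	3.0774	-0.0045	-3.6650	5'
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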