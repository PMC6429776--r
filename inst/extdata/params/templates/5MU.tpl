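# rnarefine residue template v1
residue 5MU
aliases RT
class U
kind ribo
formal_charge -1
atoms
N1	N*	N	0.0627	1.2101	-0.1890	0.8042	-
C2	C	C	0.4895	1.2228	0.2034	2.0896	-
N3	NA	N	-0.3341	2.3204	0.0409	2.8507	-
C4	C	C	0.6160	3.4283	-0.5276	2.3341	-
C5	CM	C	-0.3427	3.4286	-0.9414	0.9811	-
C7	CT	C	0.0208	4.6552	-1.5754	0.3767	-
C6	CM	C	-0.0918	2.3141	-0.7667	0.2390	-
O2	O	O	-0.5269	0.2295	0.7131	2.5704	-
O4	O	O	-0.5553	4.4219	-0.6754	3.0220	-
C1'	CT	C	0.0394	0.0000	0.0000	0.0000	-
C2'	CT	C	0.0670	-0.0299	1.4248	-0.5949	-
O2'	OH	O	-0.6139	-1.3683	1.9177	-0.6871	-
C3'	CT	C	0.2022	0.5695	1.2005	-1.9949	-
C4'	CT	C	0.1065	0.0249	-0.1915	-2.3660	-
O3'	OS	O	-0.5246	0.1481	2.1880	-2.9369	-
O4'	OS	O	-0.3548	0.0298	-0.9250	-1.1167	-
C5'	CT	C	0.0558	0.9006	-0.8562	-3.4291	-
O5'	OS	O	-0.4954	2.2577	-0.8768	-2.9839	-
P	P	P	1.1662	3.4101	-1.5611	-3.8758	-
OP1	O2	O	-0.7760	3.9915	-0.5530	-4.7897	-
OP2	O2	O	-0.7760	4.3799	-2.4275	-2.9257	-
H3	H	H	0.3154	2.3135	0.3304	3.7771	-
H71	HC	H	0.0000	5.4441	-1.6284	1.1280	-
H72	HC	H	0.0000	4.4140	-2.5802	0.0328	-
H73	HC	H	0.0000	4.9971	-0.9746	-0.4659	-
H6	H4	H	0.2188	2.2954	-1.0791	-0.7936	-
H1'	H2	H	0.2007	-0.8879	-0.1726	0.6091	-
H2'	H1	H	0.0972	0.5919	2.1005	-0.0085	-
HO2'	HO	H	0.4186	-1.5408	2.4116	0.1253	-
H3'	H1	H	0.0615	1.6584	1.1760	-1.9398	-
H4'	H1	H	0.1174	-0.9963	-0.1004	-2.7360	-
HO3'	HO	H	0.4376	0.5227	3.0311	-2.6454	3'
H5'	H1	H	0.0679	0.5576	-1.8771	-3.5963	-
H5''	H1	H	0.0679	0.8328	-0.2931	-4.3596	-
HO5'	HO	H	0.4295	2.7939	-1.2963	-3.6607	5'
bonds
N1	C2
N1	C6
N1	C1'
C2	N3
C2	O2
N3	C4
N3	H3
C4	C5
C4	O4
C5	C7
C5	C6
C7	H71
C7	H72
C7	H73
C6	H6
C1'	C2'
C1'	O4'
C1'	H1'
C2'	O2'
C2'	C3'
C2'	H2'
O2'	HO2'
C3'	C4'
C3'	O3'
C3'	H3'
C4'	O4'
C4'	C5'
C4'	H4'
O3'	HO3'
C5'	O5'
C5'	H5'
C5'	H5''
O5'	P
O5'	HO5'
P	OP1
P	OP2
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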