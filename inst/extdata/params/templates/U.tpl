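# rnarefine residue template v1
residue U
aliases RU URA URI
class U
kind ribo
formal_charge -1
atoms
P	P	P	1.1662	-2.2871	3.2371	-3.6613	-
OP1	O2	O	-0.7760	-3.7171	2.8645	-3.5891	-
OP2	O2	O	-0.7760	-1.6102	3.5215	-5.0942	-
O5'	OS	O	-0.4954	-1.4089	2.1527	-2.8586	-
C5'	CT	C	0.0558	0.0158	2.1526	-2.9472	-
C4'	CT	C	0.1065	0.5829	1.0528	-2.0487	-
O4'	OS	O	-0.3548	0.2637	1.2700	-0.6504	-
C3'	CT	C	0.2022	-0.0491	-0.3130	-2.3759	-
O3'	OS	O	-0.5246	0.5918	-0.9232	-3.4979	-
C2'	CT	C	0.0670	0.1703	-1.0982	-1.0716	-
O2'	OH	O	-0.6139	1.4856	-1.6565	-1.0285	-
C1'	CT	C	0.0394	0.0000	0.0000	0.0000	-
N1	N*	N	0.0424	-1.3749	0.0038	0.5072	-
C2	C	C	0.4695	-1.7199	-0.8310	1.5017	-
O2	O	O	-0.5469	-0.8884	-1.5844	1.9678	-
N3	NA	N	-0.3541	-2.9724	-0.8370	1.9966	-
C4	C	C	0.5960	-3.9070	-0.0074	1.4900	-
O4	O	O	-0.5753	-5.0412	-0.0163	1.9338	-
C5	CM	C	-0.3627	-3.5572	0.8727	0.4392	-
C6	CM	C	-0.1118	-2.2927	0.8621	-0.0344	-
H5'	H1	H	0.0679	0.3996	3.1204	-2.6230	-
H5''	H1	H	0.0679	0.3159	1.9698	-3.9784	-
H4'	H1	H	0.1174	1.6644	0.9954	-2.1759	-
H3'	H1	H	0.0615	-1.1155	-0.1972	-2.5707	-
HO3'	HO	H	0.4376	0.1487	-1.7704	-3.6469	3'
H2'	H1	H	0.0972	-0.5837	-1.8762	-0.9540	-
HO2'	HO	H	0.4186	1.4424	-2.4305	-0.4518	-
H1'	H2	H	0.2007	0.7024	-0.1579	0.8173	-
H3	H	H	0.3154	-3.2039	-1.4442	2.7171	-
H5	HA	H	0.1811	-4.2927	1.5445	0.0215	-
H6	H4	H	0.2188	-2.0084	1.5263	-0.8359	-
HO5'	HO	H	0.4295	-1.7494	2.8473	-3.4271	5'
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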