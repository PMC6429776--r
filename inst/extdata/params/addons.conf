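# rnarefine parameter file v1
k1 = -1.0
d = 0.16
theta0 = 180.0
k2 = 10.0
k3 = 10.0
k4 = 10.0
pair_energy_threshold = -2.0
# ideal hydrogen(H)..acceptor lengths by donor/acceptor element
HBIDEAL N N 1.84
HBIDEAL N O 1.89
HBIDEAL O N 1.85
HBIDEAL O O 1.85
# Watson-Crick H-bond rules: class1 class2 donor_class donor h acceptor_class acceptor
PAIRHB A U A N6 H61 U O4
PAIRHB A U U N3 H3 A N1
PAIRHB A T A N6 H61 T O4
PAIRHB A T T N3 H3 A N1
PAIRHB G C C N4 H41 G O6
PAIRHB G C G N1 H1 C N3
PAIRHB G C G N2 H22 C O2
# pair placement transforms (partner frame -> base frame)
PAIRT A U 0.755117 0.655590 0.000000 0.655590 -0.755117 0.000000 0.000000 0.000000 -1.000000 -2.481389 8.555158 0.000000
PAIRT U A 0.755117 0.655590 0.000000 0.655590 -0.755117 0.000000 0.000000 0.000000 -1.000000 -3.734938 8.086919 0.000000
PAIRT A T 0.772142 0.635450 0.000000 0.635450 -0.772142 0.000000 0.000000 0.000000 -1.000000 -2.270085 8.576211 0.000000
PAIRT T A 0.772142 0.635450 0.000000 0.635450 -0.772142 0.000000 0.000000 0.000000 -1.000000 -3.696921 8.064581 0.000000
PAIRT G C 0.781154 0.624339 0.000000 0.624339 -0.781154 0.000000 0.000000 0.000000 -1.000000 -2.498890 8.700374 0.000000
PAIRT C G 0.781154 0.624339 0.000000 0.624339 -0.781154 0.000000 0.000000 0.000000 -1.000000 -3.479963 8.356483 0.000000
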