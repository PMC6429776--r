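# rnarefine parameter file v1
# BOND t1 t2 k[kcal/mol/A^2] r0[A]
BOND C CB 447.0 1.4144
BOND C CM 410.0 1.4483
BOND C N* 424.0 1.3666
BOND C NA 418.0 1.3663
BOND C NC 457.0 1.3322
BOND C O 570.0 1.2221
BOND CA CB 469.0 1.4050
BOND CA CM 427.0 1.4098
BOND CA N2 481.0 1.3772
BOND CA NA 424.0 1.3621
BOND CA NC 483.0 1.3229
BOND CB CB 520.0 1.4023
BOND CB N* 436.0 1.3700
BOND CB NB 414.0 1.3550
BOND CB NC 461.0 1.3334
BOND CK H5 367.0 1.0800
BOND CK N* 440.0 1.3633
BOND CK NB 529.0 1.3013
BOND CM CM 549.0 1.3471
BOND CM CT 317.0 1.5011
BOND CM H4 367.0 1.0814
BOND CM HA 367.0 1.0810
BOND CM N* 448.0 1.3732
BOND CQ H5 367.0 1.0803
BOND CQ NC 502.0 1.3178
BOND CT CT 310.0 1.5346
BOND CT H1 340.0 1.0906
BOND CT H2 340.0 1.0911
BOND CT HC 340.0 1.0912
BOND CT N* 337.0 1.4587
BOND CT OH 320.0 1.4291
BOND CT OS 320.0 1.4368
BOND H N2 434.0 0.9699
BOND H NA 434.0 0.9856
BOND HO OH 553.0 0.9668
BOND HO OS 553.0 0.9641
BOND O2 P 525.0 1.5473
BOND OS P 230.0 1.6112
# ANGLE t1 tc t2 k[kcal/mol/rad^2] theta0[deg]
ANGLE C CB CB 63.0 118.6188
ANGLE C CB NB 63.0 134.1366
ANGLE C CM CM 63.0 118.9829
ANGLE C CM CT 63.0 119.2607
ANGLE C CM HA 50.0 119.6068
ANGLE C N* CM 63.0 120.4718
ANGLE C N* CT 63.0 120.2512
ANGLE C NA C 63.0 123.5830
ANGLE C NA CA 63.0 120.3441
ANGLE C NA H 50.0 118.5279
ANGLE C NC CA 63.0 120.6933
ANGLE CA CB CB 63.0 118.1657
ANGLE CA CB NB 63.0 134.7317
ANGLE CA CM CM 63.0 118.9974
ANGLE CA CM HA 50.0 120.4809
ANGLE CA N2 H 50.0 120.0055
ANGLE CA NA H 50.0 119.8467
ANGLE CA NC CB 63.0 121.1566
ANGLE CA NC CQ 63.0 121.1450
ANGLE CB C NA 63.0 118.3357
ANGLE CB C O 63.0 120.7990
ANGLE CB CA N2 63.0 120.7535
ANGLE CB CA NC 63.0 118.4846
ANGLE CB CB N* 63.0 106.0727
ANGLE CB CB NB 63.0 107.1705
ANGLE CB CB NC 63.0 119.3340
ANGLE CB N* CK 63.0 107.4641
ANGLE CB N* CT 63.0 126.2975
ANGLE CB NB CK 63.0 109.3862
ANGLE CB NC CQ 63.0 120.6408
ANGLE CK N* CT 63.0 126.2383
ANGLE CM C NA 63.0 117.0421
ANGLE CM C O 63.0 120.7710
ANGLE CM CA N2 63.0 120.1865
ANGLE CM CA NC 63.0 119.5954
ANGLE CM CM CT 63.0 121.9904
ANGLE CM CM H4 50.0 120.3632
ANGLE CM CM HA 50.0 120.8480
ANGLE CM CM N* 63.0 121.0104
ANGLE CM CT HC 50.0 109.6062
ANGLE CM N* CT 63.0 119.2768
ANGLE CT CT CT 63.0 105.3073
ANGLE CT CT H1 50.0 110.1516
ANGLE CT CT H2 50.0 110.4192
ANGLE CT CT HC 50.0 111.1791
ANGLE CT CT N* 63.0 110.7133
ANGLE CT CT OH 63.0 111.0051
ANGLE CT CT OS 63.0 109.4217
ANGLE CT OH HO 50.0 106.8119
ANGLE CT OS CT 60.0 109.8063
ANGLE CT OS HO 50.0 107.7019
ANGLE CT OS P 100.0 120.9000
ANGLE H N2 H 35.0 119.9886
ANGLE H1 CT H1 35.0 109.4295
ANGLE H1 CT OH 50.0 110.8212
ANGLE H1 CT OS 50.0 109.3329
ANGLE H2 CT N* 50.0 109.6596
ANGLE H2 CT OS 50.0 109.7519
ANGLE H4 CM N* 50.0 118.6261
ANGLE H5 CK N* 50.0 125.0604
ANGLE H5 CK NB 50.0 125.0340
ANGLE H5 CQ NC 50.0 118.7367
ANGLE HC CT HC 35.0 109.6106
ANGLE HO OS P 50.0 12.5316
ANGLE N* C NA 63.0 117.9799
ANGLE N* C NC 63.0 121.0877
ANGLE N* C O 63.0 120.9541
ANGLE N* CB NC 63.0 134.5930
ANGLE N* CK NB 63.0 109.9056
ANGLE N* CT OS 63.0 109.0000
ANGLE N2 CA NA 63.0 119.0470
ANGLE N2 CA NC 63.0 120.0077
ANGLE NA C O 63.0 121.1795
ANGLE NA CA NC 63.0 121.9083
ANGLE NC C O 63.0 119.4293
ANGLE NC CQ NC 63.0 122.5267
ANGLE O2 P O2 140.0 119.6200
ANGLE O2 P OS 100.0 109.3708
ANGLE OS P OS 45.0 104.0000
# TORSION t1 t2 t3 t4 k[kcal/mol] n gamma[deg] (X = wildcard)
TORSION X CT CT X 0.1556 3 0.0
TORSION X CT OS X 0.3833 3 0.0
TORSION X CT OH X 0.1667 3 0.0
TORSION X OS P X 0.2500 3 0.0
TORSION X CT N* X 0.0000 2 0.0
TORSION X CA CA X 3.6250 2 180.0
TORSION X CB CB X 5.4500 2 180.0
TORSION X CA CB X 3.5000 2 180.0
TORSION X C CB X 3.0000 2 180.0
TORSION X CK NB X 5.0000 2 180.0
TORSION X CB NB X 2.5500 2 180.0
TORSION X CK N* X 1.7000 2 180.0
TORSION X CM CM X 6.6500 2 180.0
TORSION X C CM X 2.1750 2 180.0
TORSION X CM N* X 1.8500 2 180.0
TORSION X C N* X 1.4500 2 180.0
TORSION X C NA X 1.3500 2 180.0
TORSION X CA NA X 1.5000 2 180.0
TORSION X CA NC X 4.8000 2 180.0
TORSION X CQ NC X 6.8000 2 180.0
TORSION X CB NC X 4.1500 2 180.0
TORSION X CA N2 X 2.4000 2 180.0
TORSION X C NC X 4.0000 2 180.0
TORSION X CB N* X 1.6500 2 180.0
TORSION X CM CT X 0.0000 3 0.0
TORSION X CA CM X 2.5000 2 180.0
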