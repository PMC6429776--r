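# rnarefine backbone conformer library v1
# synthetic: ideal A-form suite window plus perturbed variants
schema P OP1 OP2 O5' C5' C4' C3' O3' P+
fragment ideal_aform
1.5682 -1.5002 1.0011
1.2712 -1.9107 2.3901
2.7120 -0.4019 0.7233
0.2060 -1.0530 0.2701
0.1956 -0.7118 -1.1163
-1.2314 -0.3770 -1.5509
-1.8420 0.7110 -0.6497
-1.4280 2.0157 -1.0611
-1.4516 3.2280 -0.0065
fragment perturbed_01
1.6655 -1.4909 0.8666
1.1735 -1.9084 2.2960
2.6861 -0.3746 0.6784
0.2161 -1.1121 0.2596
0.2236 -0.7160 -1.1306
-1.2209 -0.3450 -1.4921
-1.8937 0.8380 -0.6015
-1.4053 1.9520 -1.0003
-1.3745 3.2654 0.0612
fragment perturbed_02
1.6168 -1.3676 1.1098
1.2390 -1.9027 2.3195
2.7374 -0.5042 0.5521
0.3383 -1.2488 0.1930
0.1688 -0.7612 -0.9755
-1.1151 -0.4190 -1.5966
-1.8523 0.6014 -0.5871
-1.2479 1.9593 -0.9435
-1.5218 3.1596 0.1199
fragment perturbed_03
1.6361 -1.5979 0.9016
1.2135 -2.0234 2.4568
2.5552 -0.4792 0.8128
0.1581 -1.0458 0.2030
0.2295 -0.6147 -1.1129
-1.1928 -0.2944 -1.6065
-1.8055 0.8855 -0.6439
-1.5491 1.9464 -1.0018
-1.5683 3.1431 -0.2629
fragment perturbed_04
1.6615 -1.5457 0.7624
1.2107 -1.9387 2.3662
2.6751 -0.2754 0.7893
0.0905 -1.1327 0.3643
0.0491 -0.6113 -1.0897
-1.2260 -0.1467 -1.7076
-2.2048 0.9832 -0.5897
-1.5168 2.1203 -1.1863
-1.2958 3.0808 -0.0322
fragment perturbed_05
1.5490 -1.6218 1.0924
1.1982 -1.7655 2.5789
2.6453 -0.5294 0.7051
0.5936 -1.1687 0.2462
-0.0532 -0.4026 -1.4052
-1.3303 -0.5798 -1.3342
-1.7702 0.8909 -0.6497
-1.2845 2.2780 -0.9905
-1.2818 2.9310 0.0737
fragment perturbed_06
1.6920 -1.6859 0.8101
1.4196 -2.1385 2.3846
2.8577 -0.7797 0.8680
0.0309 -0.9844 0.2715
0.2960 -0.7100 -0.9772
-1.1633 -0.2718 -1.2797
-1.9837 0.5298 -0.8926
-1.3668 2.0056 -1.3449
-1.5635 3.4717 0.2603
fragment perturbed_07
1.2885 -1.3924 1.0122
1.3741 -1.6584 2.6343
2.6200 -0.1594 0.5491
0.5840 -0.8047 0.5723
0.2960 -0.6618 -1.0957
-1.4644 -0.5057 -1.4018
-1.8238 0.6277 -0.6659
-1.4589 1.9626 -1.3751
-1.3829 3.1578 -0.0631
fragment perturbed_08
2.2834 -1.6453 1.0708
1.3885 -1.8966 2.4922
2.7909 -0.4230 0.4378
0.3294 -1.0820 0.4844
-0.2627 -1.1188 -1.0496
-1.4365 -0.2464 -1.7285
-2.0311 0.6424 -0.3806
-1.3567 1.9151 -1.1039
-1.5667 2.9754 0.1214
fragment perturbed_09
1.8326 -1.3056 0.8548
1.5793 -1.9420 2.1039
2.7356 -0.4020 0.7982
-0.0064 -1.0083 0.3490
0.0955 -0.7753 -1.2912
-1.5186 -0.7921 -1.4026
-1.7807 0.7795 -0.5114
-1.2881 2.0344 -0.9887
-1.2530 3.0498 0.0706
fragment perturbed_10
1.5007 -1.4594 0.9281
1.1603 -2.3525 2.2797
2.5486 -0.0855 0.8009
0.2280 -1.1102 -0.3295
0.3271 -0.5615 -1.0140
-1.1538 -0.5049 -1.4727
-2.0633 1.0415 -0.7012
-1.8050 1.8382 -0.6927
-1.1308 3.4992 -0.0652
fragment perturbed_11
1.8016 -1.2763 1.3388
1.4033 -1.8646 1.8287
2.7769 -0.1262 1.1819
0.4469 -1.1971 0.4183
0.6102 -0.8315 -1.2002
-1.6602 -0.0273 -1.2827
-1.6993 1.2217 -0.7096
-1.6621 2.4975 -1.3287
-1.3375 3.2872 -0.1748
fragment perturbed_12
1.8915 -1.6200 0.8511
1.6095 -1.8036 2.5046
2.4871 -0.4565 0.6187
0.2035 -1.1074 0.2104
0.4361 -0.7907 -1.1565
-1.2042 -0.4794 -2.1166
-2.0405 0.7878 -0.8588
-2.2148 1.9387 -1.2376
-1.5058 3.5961 0.1532
fragment perturbed_13
1.6042 -1.4968 0.9888
0.9560 -2.4199 3.0166
2.7424 0.0773 0.4026
0.2640 -0.9507 0.7207
-0.1469 -0.4803 -0.6931
-1.2639 -0.6958 -1.9600
-1.3835 0.4195 -0.6599
-1.1832 2.0053 -0.9772
-1.3584 3.2463 0.0522
fragment perturbed_14
2.5779 -1.1821 0.6644
0.5728 -2.1429 1.5286
2.7244 -0.6338 0.7252
0.4883 -0.9909 0.2144
0.5116 -0.7784 -1.0968
-1.0674 0.2398 -2.1110
-2.0927 1.1536 -0.8071
-1.6264 2.0173 -1.1406
-1.4368 2.9174 -0.5468
fragment perturbed_15
2.0692 -1.7616 0.8379
1.0767 -1.6945 2.1538
2.3672 -0.0962 0.9150
-0.4131 -0.6698 0.3082
0.4578 -0.1999 -0.8708
-0.9387 -0.0292 -1.9754
-1.4248 0.7567 -0.4548
-1.2295 2.1640 -0.5051
-1.3512 3.2811 0.5985
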