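track type=bedGraph name=markB
chr1	925	950	0.5557
chr1	950	975	0.0490
chr1	975	1000	-0.6595
chr1	1000	1025	0.1407
chr1	1025	1050	0.0690
chr1	1050	1075	0.1830
chr1	1075	1100	-0.0470
chr1	1100	1125	0.4584
chr1	1125	1150	1.8325
chr1	1150	1175	3.2926
chr1	1175	1200	4.3414
chr1	1200	1225	6.3928
chr1	1225	1250	7.3427
chr1	1250	1275	6.4068
chr1	1275	1300	4.7105
chr1	1300	1325	2.4299
chr1	1325	1350	1.7318
chr1	1350	1375	0.9321
chr1	1375	1400	0.1569
chr1	1400	1425	0.0524
chr1	1750	1775	0.6760
chr1	1775	1800	0.7422
chr1	1800	1825	0.9387
chr1	1825	1850	1.4277
chr1	1850	1875	3.5145
chr1	1875	1900	4.8492
chr1	1900	1925	6.3659
chr1	1925	1950	7.3403
chr1	1950	1975	6.9057
chr1	1975	2000	4.8963
chr1	2000	2025	3.7037
chr1	2025	2050	1.6888
chr1	2050	2075	0.5035
chr1	2075	2100	0.2882
chr1	2100	2125	-0.4314
chr1	2125	2150	-0.9186
chr1	2150	2175	-0.3355
chr1	2175	2200	0.0887
chr1	2200	2225	-0.1454
chr1	2225	2250	-0.4124
chr1	2400	2425	0.1928
chr1	2425	2450	-0.5465
chr1	2450	2475	0.5329
chr1	2475	2500	-0.5515
chr1	2500	2525	-0.4515
chr1	2525	2550	-0.4147
chr1	2550	2575	0.4034
chr1	2575	2600	0.0627
chr1	2600	2625	1.5426
chr1	2625	2650	2.6789
chr1	2650	2675	4.7283
chr1	2675	2700	6.3622
chr1	2700	2725	7.3875
chr1	2725	2750	6.2882
chr1	2750	2775	4.7871
chr1	2775	2800	2.9959
chr1	2800	2825	1.1138
chr1	2825	2850	0.8743
chr1	2850	2875	0.2834
chr1	2875	2900	0.2484
chr1	3125	3150	-0.6843
chr1	3150	3175	0.6233
chr1	3175	3200	0.5534
chr1	3200	3225	1.6806
chr1	3225	3250	2.9988
chr1	3250	3275	4.5516
chr1	3275	3300	6.6565
chr1	3300	3325	7.4305
chr1	3325	3350	6.2961
chr1	3350	3375	4.7790
chr1	3375	3400	3.0761
chr1	3400	3425	1.2879
chr1	3425	3450	1.0332
chr1	3450	3475	-0.2650
chr1	3475	3500	0.2502
chr1	3500	3525	0.0877
chr1	3525	3550	-0.0746
chr1	3550	3575	-0.1513
chr1	3575	3600	0.5544
chr1	3600	3625	0.0543
chr1	3825	3850	-0.1211
chr1	3850	3875	-0.2178
chr1	3875	3900	0.2475
chr1	3900	3925	-0.2052
chr1	3925	3950	0.6819
chr1	3950	3975	0.4984
chr1	3975	4000	0.5900
chr1	4000	4025	1.4250
chr1	4025	4050	1.3090
chr1	4050	4075	3.2304
chr1	4075	4100	4.8495
chr1	4100	4125	7.3585
chr1	4125	4150	7.5364
chr1	4150	4175	6.2228
chr1	4175	4200	4.8098
chr1	4200	4225	2.6394
chr1	4225	4250	1.3878
chr1	4250	4275	0.5797
chr1	4275	4300	0.0362
chr1	4300	4325	0.1679
chr1	4500	4525	0.1438
chr1	4525	4550	-0.1797
chr1	4550	4575	0.4366
chr1	4575	4600	0.1206
chr1	4600	4625	0.0498
chr1	4625	4650	-0.1723
chr1	4650	4675	-0.1033
chr1	4675	4700	0.3842
chr1	4700	4725	1.2636
chr1	4725	4750	3.0310
chr1	4750	4775	4.7317
chr1	4775	4800	6.4693
chr1	4800	4825	7.0735
chr1	4825	4850	6.0629
chr1	4850	4875	5.0967
chr1	4875	4900	2.6700
chr1	4900	4925	1.4602
chr1	4925	4950	0.5539
chr1	4950	4975	-0.0605
chr1	4975	5000	-0.0142
chr1	5275	5300	-0.7282
chr1	5300	5325	0.2427
chr1	5325	5350	0.4463
chr1	5350	5375	1.1446
chr1	5375	5400	2.7661
chr1	5400	5425	4.3967
chr1	5425	5450	5.9032
chr1	5450	5475	6.7292
chr1	5475	5500	6.4315
chr1	5500	5525	4.6660
chr1	5525	5550	3.4271
chr1	5550	5575	1.6599
chr1	5575	5600	0.6953
chr1	5600	5625	0.5830
chr1	5625	5650	0.7607
chr1	5650	5675	0.4813
chr1	5675	5700	-0.4178
chr1	5700	5725	0.0463
chr1	5725	5750	0.1070
chr1	5750	5775	0.1413
chr1	5975	6000	0.2999
chr1	6000	6025	-0.3593
chr1	6025	6050	0.6632
chr1	6050	6075	1.7691
chr1	6075	6100	2.7582
chr1	6100	6125	4.2291
chr1	6125	6150	5.6644
chr1	6150	6175	6.4667
chr1	6175	6200	6.3940
chr1	6200	6225	4.7584
chr1	6225	6250	2.4239
chr1	6250	6275	1.4193
chr1	6275	6300	0.2509
chr1	6300	6325	0.0977
chr1	6325	6350	0.0647
chr1	6350	6375	-0.1964
chr1	6375	6400	0.2885
chr1	6400	6425	-0.4102
chr1	6425	6450	-0.3781
chr1	6450	6475	0.7153
chr1	6675	6700	-0.5255
chr1	6700	6725	-0.9200
chr1	6725	6750	0.7111
chr1	6750	6775	0.1881
chr1	6775	6800	-0.5152
chr1	6800	6825	-0.1285
chr1	6825	6850	0.6693
chr1	6850	6875	1.0204
chr1	6875	6900	1.3948
chr1	6900	6925	3.5172
chr1	6925	6950	5.0333
chr1	6950	6975	6.9657
chr1	6975	7000	6.9647
chr1	7000	7025	6.3772
chr1	7025	7050	5.0005
chr1	7050	7075	2.4407
chr1	7075	7100	1.1156
chr1	7100	7125	1.0479
chr1	7125	7150	-0.0030
chr1	7150	7175	-0.3607
chr1	7375	7400	-0.3087
chr1	7400	7425	0.1102
chr1	7425	7450	-0.7532
chr1	7450	7475	-0.1365
chr1	7475	7500	-0.1021
chr1	7500	7525	-0.3715
chr1	7525	7550	-0.1978
chr1	7550	7575	1.2960
chr1	7575	7600	1.4872
chr1	7600	7625	3.0882
chr1	7625	7650	4.2459
chr1	7650	7675	6.5674
chr1	7675	7700	6.8692
chr1	7700	7725	5.7341
chr1	7725	7750	4.3646
chr1	7750	7775	3.3888
chr1	7775	7800	1.6554
chr1	7800	7825	0.3954
chr1	7825	7850	0.4291
chr1	7850	7875	0.2501
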