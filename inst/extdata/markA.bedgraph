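track type=bedGraph name=markA
chr1	925	950	0.2009
chr1	950	975	0.6294
chr1	975	1000	2.2170
chr1	1000	1025	4.5681
chr1	1025	1050	7.4950
chr1	1050	1075	8.5117
chr1	1075	1100	7.1746
chr1	1100	1125	4.5051
chr1	1125	1150	1.5981
chr1	1150	1175	1.0111
chr1	1175	1200	0.0884
chr1	1200	1225	-0.2477
chr1	1225	1250	-0.2008
chr1	1250	1275	0.1008
chr1	1275	1300	0.2948
chr1	1300	1325	-0.5532
chr1	1325	1350	-0.4259
chr1	1350	1375	0.0024
chr1	1375	1400	-0.0059
chr1	1400	1425	0.1012
chr1	1750	1775	0.5264
chr1	1775	1800	-0.2357
chr1	1800	1825	0.0171
chr1	1825	1850	0.2202
chr1	1850	1875	-0.0511
chr1	1875	1900	0.3059
chr1	1900	1925	-0.6542
chr1	1925	1950	-0.3908
chr1	1950	1975	0.1484
chr1	1975	2000	-0.3716
chr1	2000	2025	0.7469
chr1	2025	2050	1.9161
chr1	2050	2075	4.4793
chr1	2075	2100	7.9225
chr1	2100	2125	8.7489
chr1	2125	2150	7.3602
chr1	2150	2175	4.5667
chr1	2175	2200	2.4578
chr1	2200	2225	-0.3350
chr1	2225	2250	0.1507
chr1	2400	2425	0.3507
chr1	2425	2450	0.4471
chr1	2450	2475	2.0510
chr1	2475	2500	4.0284
chr1	2500	2525	7.7991
chr1	2525	2550	9.4513
chr1	2550	2575	7.6667
chr1	2575	2600	4.9687
chr1	2600	2625	2.3720
chr1	2625	2650	0.8960
chr1	2650	2675	-0.0898
chr1	2675	2700	-0.3499
chr1	2700	2725	-0.0415
chr1	2725	2750	0.0520
chr1	2750	2775	-0.4287
chr1	2775	2800	0.2078
chr1	2800	2825	-0.5356
chr1	2825	2850	0.1987
chr1	2850	2875	0.4554
chr1	2875	2900	-0.1732
chr1	3125	3150	0.0806
chr1	3150	3175	0.2297
chr1	3175	3200	-0.0348
chr1	3200	3225	-0.3894
chr1	3225	3250	0.1090
chr1	3250	3275	0.5963
chr1	3275	3300	0.1068
chr1	3300	3325	0.5376
chr1	3325	3350	0.3653
chr1	3350	3375	0.5469
chr1	3375	3400	0.8055
chr1	3400	3425	1.8212
chr1	3425	3450	4.9379
chr1	3450	3475	7.8229
chr1	3475	3500	9.0998
chr1	3500	3525	7.7179
chr1	3525	3550	4.7700
chr1	3550	3575	2.4862
chr1	3575	3600	0.3650
chr1	3600	3625	0.0417
chr1	3825	3850	0.3382
chr1	3850	3875	0.9698
chr1	3875	3900	2.4166
chr1	3900	3925	4.7680
chr1	3925	3950	7.3306
chr1	3950	3975	8.9595
chr1	3975	4000	7.7545
chr1	4000	4025	4.3109
chr1	4025	4050	1.9947
chr1	4050	4075	0.9291
chr1	4075	4100	-0.5313
chr1	4100	4125	-0.1644
chr1	4125	4150	0.3382
chr1	4150	4175	0.3400
chr1	4175	4200	0.1372
chr1	4200	4225	0.6557
chr1	4225	4250	-0.0820
chr1	4250	4275	0.2969
chr1	4275	4300	0.2074
chr1	4300	4325	-0.2226
chr1	4500	4525	0.1779
chr1	4525	4550	-0.2698
chr1	4550	4575	0.4909
chr1	4575	4600	2.0390
chr1	4600	4625	4.0690
chr1	4625	4650	7.1694
chr1	4650	4675	8.7848
chr1	4675	4700	7.1863
chr1	4700	4725	4.8248
chr1	4725	4750	1.5087
chr1	4750	4775	1.2630
chr1	4775	4800	0.9311
chr1	4800	4825	0.1881
chr1	4825	4850	0.0174
chr1	4850	4875	0.4024
chr1	4875	4900	-0.6192
chr1	4900	4925	0.1401
chr1	4925	4950	-0.1184
chr1	4950	4975	-0.2417
chr1	4975	5000	0.0741
chr1	5275	5300	0.6410
chr1	5300	5325	-0.1189
chr1	5325	5350	0.5491
chr1	5350	5375	-0.0402
chr1	5375	5400	-0.0068
chr1	5400	5425	-0.2592
chr1	5425	5450	0.0714
chr1	5450	5475	-0.3980
chr1	5475	5500	0.2953
chr1	5500	5525	0.6914
chr1	5525	5550	1.7460
chr1	5550	5575	5.0823
chr1	5575	5600	7.4848
chr1	5600	5625	8.6230
chr1	5625	5650	7.6488
chr1	5650	5675	4.9075
chr1	5675	5700	2.4698
chr1	5700	5725	1.0895
chr1	5725	5750	0.5388
chr1	5750	5775	-0.2409
chr1	5975	6000	-0.1300
chr1	6000	6025	0.2650
chr1	6025	6050	0.2652
chr1	6050	6075	0.0976
chr1	6075	6100	0.4743
chr1	6100	6125	0.1634
chr1	6125	6150	-0.5258
chr1	6150	6175	-0.7402
chr1	6175	6200	0.5391
chr1	6200	6225	0.4344
chr1	6225	6250	2.6913
chr1	6250	6275	4.0841
chr1	6275	6300	7.9992
chr1	6300	6325	9.9475
chr1	6325	6350	8.2133
chr1	6350	6375	4.3857
chr1	6375	6400	2.3221
chr1	6400	6425	1.1764
chr1	6425	6450	0.2372
chr1	6450	6475	0.1098
chr1	6675	6700	0.0307
chr1	6700	6725	0.2837
chr1	6725	6750	0.4714
chr1	6750	6775	2.1564
chr1	6775	6800	4.2636
chr1	6800	6825	7.7865
chr1	6825	6850	9.1254
chr1	6850	6875	7.3824
chr1	6875	6900	4.1729
chr1	6900	6925	1.8970
chr1	6925	6950	0.7847
chr1	6950	6975	0.0973
chr1	6975	7000	-0.8718
chr1	7000	7025	-0.0009
chr1	7025	7050	-0.3773
chr1	7050	7075	0.1034
chr1	7075	7100	0.1283
chr1	7100	7125	0.3210
chr1	7125	7150	0.4670
chr1	7150	7175	-0.5429
chr1	7375	7400	0.0319
chr1	7400	7425	0.7048
chr1	7425	7450	0.5344
chr1	7450	7475	1.5711
chr1	7475	7500	4.9922
chr1	7500	7525	7.0691
chr1	7525	7550	9.2403
chr1	7550	7575	7.3472
chr1	7575	7600	4.5488
chr1	7600	7625	1.6921
chr1	7625	7650	0.7591
chr1	7650	7675	0.2364
chr1	7675	7700	-0.0669
chr1	7700	7725	-0.0348
chr1	7725	7750	0.1605
chr1	7750	7775	0.2877
chr1	7775	7800	-0.8541
chr1	7800	7825	-0.4479
chr1	7825	7850	0.3049
chr1	7850	7875	0.0025
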