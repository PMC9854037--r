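element,Z,A,energy_mev,mu_rho,mu_en_rho
H,1,1.008,0.01,0.3854,0.00985
H,1,1.008,0.015,0.3764,0.0111
H,1,1.008,0.02,0.3695,0.01327
H,1,1.008,0.03,0.357,0.01868
H,1,1.008,0.04,0.3458,0.02315
H,1,1.008,0.05,0.3355,0.02709
H,1,1.008,0.06,0.326,0.03053
H,1,1.008,0.08,0.3091,0.0362
H,1,1.008,0.1,0.2944,0.04063
H,1,1.008,0.15,0.2651,0.04813
H,1,1.008,0.2,0.2429,0.05254
H,1,1.008,0.3,0.2112,0.05695
H,1,1.008,0.4,0.1893,0.0586
H,1,1.008,0.5,0.1729,0.059
H,1,1.008,0.6,0.1599,0.05875
H,1,1.008,0.8,0.1405,0.05739
H,1,1.008,1,0.1263,0.05556
H,1,1.008,1.25,0.1129,0.05311
H,1,1.008,1.5,0.1027,0.05075
C,6,12.011,0.01,2.373,2.078
C,6,12.011,0.015,0.8071,0.5627
C,6,12.011,0.02,0.442,0.2238
C,6,12.011,0.03,0.2562,0.06614
C,6,12.011,0.04,0.2076,0.03343
C,6,12.011,0.05,0.1871,0.02397
C,6,12.011,0.06,0.1753,0.02098
C,6,12.011,0.08,0.161,0.02037
C,6,12.011,0.1,0.1514,0.02147
C,6,12.011,0.15,0.1347,0.02449
C,6,12.011,0.2,0.1229,0.02655
C,6,12.011,0.3,0.1066,0.0287
C,6,12.011,0.4,0.09546,0.0295
C,6,12.011,0.5,0.08715,0.02969
C,6,12.011,0.6,0.08058,0.02956
C,6,12.011,0.8,0.07076,0.02885
C,6,12.011,1,0.06361,0.02792
C,6,12.011,1.25,0.0569,0.02669
C,6,12.011,1.5,0.05179,0.02551
N,7,14.007,0.01,3.79024,3.63783
N,7,14.007,0.015,1.18344,0.957405
N,7,14.007,0.02,0.588118,0.368683
N,7,14.007,0.03,0.295202,0.0996718
N,7,14.007,0.04,0.223405,0.0445408
N,7,14.007,0.05,0.195103,0.0283017
N,7,14.007,0.06,0.180015,0.0227511
N,7,14.007,0.08,0.163057,0.0205374
N,7,14.007,0.1,0.152548,0.0212934
N,7,14.007,0.15,0.135228,0.0243266
N,7,14.007,0.2,0.123194,0.0264618
N,7,14.007,0.3,0.106739,0.028673
N,7,14.007,0.4,0.095578,0.0294929
N,7,14.007,0.5,0.0871939,0.0296788
N,7,14.007,0.6,0.0806262,0.0295587
N,7,14.007,0.8,0.0708152,0.0288529
N,7,14.007,1,0.0636395,0.0279238
N,7,14.007,1.25,0.0569281,0.0266973
N,7,14.007,1.5,0.0517993,0.0255057
O,8,15.999,0.01,5.9519,5.56571
O,8,15.999,0.015,1.83637,1.54573
O,8,15.999,0.02,0.865053,0.617966
O,8,15.999,0.03,0.377944,0.172965
O,8,15.999,0.04,0.258535,0.0753063
O,8,15.999,0.05,0.213216,0.0441376
O,8,15.999,0.06,0.190767,0.0320726
O,8,15.999,0.08,0.1679,0.024681
O,8,15.999,0.1,0.155114,0.0235486
O,8,15.999,0.15,0.13606,0.0250582
O,8,15.999,0.2,0.123657,0.0267884
O,8,15.999,0.3,0.106932,0.0287662
O,8,15.999,0.4,0.0956168,0.0295379
O,8,15.999,0.5,0.0872902,0.0297127
O,8,15.999,0.6,0.0806971,0.0295753
O,8,15.999,0.8,0.0708569,0.0288684
O,8,15.999,1,0.0637169,0.0279392
O,8,15.999,1.25,0.0569716,0.026694
O,8,15.999,1.5,0.0518498,0.0255051
Si,14,28.085,0.01,41.493,33.2965
Si,14,28.085,0.015,13.9792,11.9906
Si,14,28.085,0.02,6.36697,5.60333
Si,14,28.085,0.03,2.12019,1.88032
Si,14,28.085,0.04,1.01388,0.881456
Si,14,28.085,0.05,0.604922,0.506059
Si,14,28.085,0.06,0.418746,0.332043
Si,14,28.085,0.08,0.264383,0.182296
Si,14,28.085,0.1,0.20452,0.119785
Si,14,28.085,0.15,0.150623,0.0610545
Si,14,28.085,0.2,0.129787,0.042892
Si,14,28.085,0.3,0.108722,0.0332497
Si,14,28.085,0.4,0.0963287,0.0311429
Si,14,28.085,0.5,0.0875493,0.0303207
Si,14,28.085,0.6,0.080796,0.0297427
Si,14,28.085,0.8,0.0708037,0.028685
Si,14,28.085,1,0.0635812,0.0276067
Si,14,28.085,1.25,0.0570054,0.0263397
Si,14,28.085,1.5,0.051924,0.0250954
Ar,18,39.948,0.01,68.4121,54.8981
Ar,18,39.948,0.015,22.9555,19.69
Ar,18,39.948,0.02,10.3809,9.13582
Ar,18,39.948,0.03,3.36881,2.98768
Ar,18,39.948,0.04,1.54516,1.34334
Ar,18,39.948,0.05,0.873332,0.730602
Ar,18,39.948,0.06,0.569295,0.45142
Ar,18,39.948,0.08,0.320616,0.22107
Ar,18,39.948,0.1,0.227221,0.133081
Ar,18,39.948,0.15,0.149211,0.0604822
Ar,18,39.948,0.2,0.123125,0.0406902
Ar,18,39.948,0.3,0.100233,0.0306537
Ar,18,39.948,0.4,0.0880172,0.0284558
Ar,18,39.948,0.5,0.0796922,0.0275996
Ar,18,39.948,0.6,0.0734021,0.0270208
Ar,18,39.948,0.8,0.0642018,0.0260104
Ar,18,39.948,1,0.0576044,0.0250115
Ar,18,39.948,1.25,0.051611,0.0238472
Ar,18,39.948,1.5,0.0470423,0.022736
Ti,22,47.867,0.01,112.844,90.5534
Ti,22,47.867,0.015,37.7938,32.4174
Ti,22,47.867,0.02,17.0339,14.9909
Ti,22,47.867,0.03,5.45989,4.84218
Ti,22,47.867,0.04,2.45209,2.13181
Ti,22,47.867,0.05,1.34579,1.12585
Ti,22,47.867,0.06,0.846523,0.671247
Ti,22,47.867,0.08,0.440786,0.303929
Ti,22,47.867,0.1,0.290784,0.170308
Ti,22,47.867,0.15,0.170398,0.0690701
Ti,22,47.867,0.2,0.133684,0.0441798
Ti,22,47.867,0.3,0.104969,0.0321021
Ti,22,47.867,0.4,0.0910961,0.0294512
Ti,22,47.867,0.5,0.0820622,0.0284204
Ti,22,47.867,0.6,0.0753872,0.0277516
Ti,22,47.867,0.8,0.0657684,0.0266451
Ti,22,47.867,1,0.0589427,0.0255927
Ti,22,47.867,1.25,0.0527293,0.0243639
Ti,22,47.867,1.5,0.0480941,0.0232443
Cr,24,51.996,0.01,139.604,112.027
Cr,24,51.996,0.015,46.7295,40.0819
Cr,24,51.996,0.02,21.0396,18.5162
Cr,24,51.996,0.03,6.71807,5.95802
Cr,24,51.996,0.04,2.99712,2.60565
Cr,24,51.996,0.05,1.62918,1.36292
Cr,24,51.996,0.06,1.01236,0.802744
Cr,24,51.996,0.08,0.512083,0.353089
Cr,24,51.996,0.1,0.328038,0.192128
Cr,24,51.996,0.15,0.182232,0.0738672
Cr,24,51.996,0.2,0.139195,0.0460011
Cr,24,51.996,0.3,0.107084,0.0327488
Cr,24,51.996,0.4,0.0922894,0.029837
Cr,24,51.996,0.5,0.082886,0.0287057
Cr,24,51.996,0.6,0.0760245,0.0279862
Cr,24,51.996,0.8,0.0662215,0.0268287
Cr,24,51.996,1,0.059308,0.0257512
Cr,24,51.996,1.25,0.0529976,0.0244879
Cr,24,51.996,1.5,0.0483552,0.0233705
Mn,25,54.938,0.01,151.783,121.8
Mn,25,54.938,0.015,50.7942,43.5684
Mn,25,54.938,0.02,22.8603,20.1185
Mn,25,54.938,0.03,7.28813,6.46358
Mn,25,54.938,0.04,3.24263,2.8191
Mn,25,54.938,0.05,1.75567,1.46874
Mn,25,54.938,0.06,1.08541,0.860671
Mn,25,54.938,0.08,0.542229,0.373876
Mn,25,54.938,0.1,0.342798,0.200772
Mn,25,54.938,0.15,0.18564,0.0752484
Mn,25,54.938,0.2,0.13989,0.0462307
Mn,25,54.938,0.3,0.106469,0.0325608
Mn,25,54.938,0.4,0.0914193,0.0295557
Mn,25,54.938,0.5,0.0819704,0.0283886
Mn,25,54.938,0.6,0.0751207,0.0276535
Mn,25,54.938,0.8,0.0653792,0.0264874
Mn,25,54.938,1,0.0585316,0.0254141
Mn,25,54.938,1.25,0.0522706,0.0241519
Mn,25,54.938,1.5,0.0476999,0.0230538
Fe,26,55.845,0.01,170.6,136.9
Fe,26,55.845,0.015,57.08,48.96
Fe,26,55.845,0.02,25.68,22.6
Fe,26,55.845,0.03,8.176,7.251
Fe,26,55.845,0.04,3.629,3.155
Fe,26,55.845,0.05,1.958,1.638
Fe,26,55.845,0.06,1.205,0.9555
Fe,26,55.845,0.08,0.5952,0.4104
Fe,26,55.845,0.1,0.3717,0.2177
Fe,26,55.845,0.15,0.1964,0.07961
Fe,26,55.845,0.2,0.146,0.04825
Fe,26,55.845,0.3,0.1099,0.03361
Fe,26,55.845,0.4,0.094,0.03039
Fe,26,55.845,0.5,0.08414,0.02914
Fe,26,55.845,0.6,0.07704,0.02836
Fe,26,55.845,0.8,0.06699,0.02714
Fe,26,55.845,1,0.05995,0.02603
Fe,26,55.845,1.25,0.0535,0.02472
Fe,26,55.845,1.5,0.04883,0.0236
Co,27,58.933,0.01,183.778,147.475
Co,27,58.933,0.015,61.4782,52.7325
Co,27,58.933,0.02,27.65,24.3337
Co,27,58.933,0.03,8.79271,7.79794
Co,27,58.933,0.04,3.89453,3.38585
Co,27,58.933,0.05,2.09475,1.7524
Co,27,58.933,0.06,1.28392,1.01808
Co,27,58.933,0.08,0.627703,0.432811
Co,27,58.933,0.1,0.387559,0.226988
Co,27,58.933,0.15,0.199986,0.0810637
Co,27,58.933,0.2,0.146659,0.0484679
Co,27,58.933,0.3,0.109155,0.033382
Co,27,58.933,0.4,0.0929866,0.0300624
Co,27,58.933,0.5,0.0830837,0.0287742
Co,27,58.933,0.6,0.0760014,0.0279777
Co,27,58.933,0.8,0.0660252,0.0267491
Co,27,58.933,1,0.059062,0.0256444
Co,27,58.933,1.25,0.0526677,0.0243354
Co,27,58.933,1.5,0.0480785,0.0232368
Ni,28,58.693,0.01,208.8,167.554
Ni,28,58.693,0.015,69.8379,59.903
Ni,28,58.693,0.02,31.401,27.6348
Ni,28,58.693,0.03,9.97504,8.8465
Ni,28,58.693,0.04,4.40999,3.83398
Ni,28,58.693,0.05,2.36544,1.97885
Ni,28,58.693,0.06,1.44456,1.14546
Ni,28,58.693,0.08,0.699671,0.482435
Ni,28,58.693,0.1,0.427451,0.250353
Ni,28,58.693,0.15,0.21561,0.0873968
Ni,28,58.693,0.2,0.15599,0.0515516
Ni,28,58.693,0.3,0.114765,0.0350979
Ni,28,58.693,0.4,0.097358,0.0314756
Ni,28,58.693,0.5,0.0868268,0.0300705
Ni,28,58.693,0.6,0.0793473,0.0292094
Ni,28,58.693,0.8,0.0688644,0.0278994
Ni,28,58.693,1,0.0615749,0.0267355
Ni,28,58.693,1.25,0.0548638,0.0253501
Ni,28,58.693,1.5,0.0500916,0.0242097
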