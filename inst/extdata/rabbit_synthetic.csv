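28,0
27.99,0.489
27.959,0.976
27.907,1.463
27.836,1.946
27.744,2.427
27.633,2.904
27.503,3.377
27.354,3.844
27.187,4.306
27.003,4.761
26.802,5.21
26.585,5.651
26.352,6.084
26.105,6.509
25.845,6.925
25.571,7.333
25.286,7.731
24.989,8.12
24.682,8.499
24.366,8.868
24.04,9.228
23.707,9.578
23.366,9.918
23.018,10.248
22.665,10.569
22.307,10.88
21.943,11.181
21.576,11.472
21.205,11.754
20.832,12.027
20.456,12.291
20.078,12.546
19.698,12.792
19.318,13.03
18.936,13.259
18.554,13.481
18.172,13.694
17.791,13.9
17.409,14.098
17.029,14.289
16.649,14.472
16.27,14.649
15.892,14.82
15.516,14.984
15.141,15.141
14.768,15.293
14.397,15.439
14.029,15.581
13.663,15.718
13.302,15.853
12.948,15.989
12.603,16.131
12.275,16.29
11.973,16.48
11.71,16.723
11.504,17.055
11.377,17.519
11.356,18.173
11.465,19.081
11.726,20.31
12.147,21.914
12.72,23.923
13.413,26.325
14.169,29.051
14.907,31.968
15.532,34.886
15.948,37.572
16.073,39.782
15.852,41.297
15.272,41.959
14.359,41.7
13.177,40.556
11.818,38.655
10.38,36.201
8.959,33.434
7.628,30.593
6.438,27.887
5.413,25.468
4.554,23.426
3.842,21.791
3.254,20.547
2.761,19.645
2.336,19.023
1.956,18.614
1.606,18.362
1.274,18.222
0.952,18.162
0.634,18.168
0.318,18.239
0,18.392
-0.326,18.657
-0.666,19.081
-1.034,19.723
-1.444,20.648
-1.918,21.923
-2.48,23.597
-3.154,25.69
-3.96,28.174
-4.903,30.957
-5.975,33.887
-7.144,36.752
-8.355,39.307
-9.536,41.303
-10.604,42.531
-11.482,42.853
-12.109,42.229
-12.451,40.725
-12.509,38.497
-12.317,35.771
-11.937,32.795
-11.443,29.811
-10.915,27.016
-10.42,24.549
-10.011,22.484
-9.716,20.836
-9.548,19.577
-9.503,18.651
-9.565,17.989
-9.715,17.526
-9.932,17.203
-10.198,16.972
-10.497,16.799
-10.819,16.66
-11.155,16.539
-11.501,16.425
-11.853,16.314
-12.209,16.202
-12.568,16.086
-12.929,15.967
-13.293,15.842
-13.659,15.713
-14.027,15.578
-14.397,15.438
-14.768,15.293
-15.141,15.141
-15.516,14.984
-15.892,14.82
-16.27,14.649
-16.649,14.472
-17.029,14.289
-17.409,14.098
-17.791,13.9
-18.172,13.694
-18.554,13.481
-18.936,13.259
-19.318,13.03
-19.698,12.792
-20.078,12.546
-20.456,12.291
-20.832,12.027
-21.205,11.754
-21.576,11.472
-21.943,11.181
-22.307,10.88
-22.665,10.569
-23.018,10.248
-23.366,9.918
-23.707,9.578
-24.04,9.228
-24.366,8.868
-24.682,8.499
-24.989,8.12
-25.286,7.731
-25.571,7.333
-25.845,6.925
-26.105,6.509
-26.352,6.084
-26.585,5.651
-26.802,5.21
-27.003,4.761
-27.187,4.306
-27.354,3.844
-27.503,3.377
-27.633,2.904
-27.744,2.427
-27.836,1.946
-27.907,1.463
-27.959,0.976
-27.99,0.489
-28,0
-27.99,-0.489
-27.959,-0.976
-27.907,-1.463
-27.836,-1.946
-27.744,-2.427
-27.633,-2.904
-27.503,-3.377
-27.354,-3.844
-27.187,-4.306
-27.003,-4.761
-26.802,-5.21
-26.585,-5.651
-26.352,-6.084
-26.105,-6.509
-25.845,-6.925
-25.571,-7.333
-25.286,-7.731
-24.989,-8.12
-24.682,-8.499
-24.366,-8.868
-24.04,-9.228
-23.707,-9.578
-23.366,-9.918
-23.018,-10.248
-22.665,-10.569
-22.307,-10.88
-21.943,-11.181
-21.576,-11.472
-21.205,-11.754
-20.832,-12.027
-20.456,-12.291
-20.078,-12.546
-19.698,-12.792
-19.318,-13.03
-18.936,-13.259
-18.554,-13.481
-18.172,-13.694
-17.791,-13.9
-17.409,-14.098
-17.029,-14.289
-16.649,-14.472
-16.27,-14.649
-15.892,-14.82
-15.516,-14.984
-15.141,-15.141
-14.768,-15.293
-14.397,-15.438
-14.027,-15.578
-13.659,-15.713
-13.293,-15.842
-12.929,-15.966
-12.567,-16.085
-12.207,-16.199
-11.849,-16.309
-11.493,-16.414
-11.139,-16.514
-10.787,-16.611
-10.437,-16.703
-10.089,-16.791
-9.743,-16.875
-9.399,-16.956
-9.056,-17.032
-8.716,-17.106
-8.377,-17.176
-8.04,-17.242
-7.705,-17.305
-7.371,-17.365
-7.039,-17.422
-6.708,-17.476
-6.379,-17.527
-6.051,-17.575
-5.725,-17.62
-5.4,-17.662
-5.076,-17.702
-4.753,-17.739
-4.431,-17.773
-4.111,-17.805
-3.791,-17.834
-3.472,-17.861
-3.154,-17.885
-2.836,-17.907
-2.519,-17.927
-2.203,-17.944
-1.888,-17.959
-1.572,-17.972
-1.257,-17.982
-0.943,-17.99
-0.628,-17.995
-0.314,-17.999
0,-18
0.314,-17.999
0.628,-17.995
0.943,-17.99
1.257,-17.982
1.572,-17.972
1.888,-17.959
2.203,-17.944
2.519,-17.927
2.836,-17.907
3.154,-17.885
3.472,-17.861
3.791,-17.834
4.111,-17.805
4.431,-17.773
4.753,-17.739
5.076,-17.702
5.4,-17.662
5.725,-17.62
6.051,-17.575
6.379,-17.527
6.708,-17.476
7.039,-17.422
7.371,-17.365
7.705,-17.305
8.04,-17.242
8.377,-17.176
8.716,-17.106
9.056,-17.032
9.399,-16.956
9.743,-16.875
10.089,-16.791
10.437,-16.703
10.787,-16.611
11.139,-16.514
11.493,-16.414
11.849,-16.309
12.207,-16.199
12.567,-16.085
12.929,-15.966
13.293,-15.842
13.659,-15.713
14.027,-15.578
14.397,-15.438
14.768,-15.293
15.141,-15.141
15.516,-14.984
15.892,-14.82
16.27,-14.649
16.649,-14.472
17.029,-14.289
17.409,-14.098
17.791,-13.9
18.172,-13.694
18.554,-13.481
18.936,-13.259
19.318,-13.03
19.698,-12.792
20.078,-12.546
20.456,-12.291
20.832,-12.027
21.205,-11.754
21.576,-11.472
21.943,-11.181
22.307,-10.88
22.665,-10.569
23.018,-10.248
23.366,-9.918
23.707,-9.578
24.04,-9.228
24.366,-8.868
24.682,-8.499
24.989,-8.12
25.286,-7.731
25.571,-7.333
25.845,-6.925
26.105,-6.509
26.352,-6.084
26.585,-5.651
26.802,-5.21
27.003,-4.761
27.187,-4.306
27.354,-3.844
27.503,-3.377
27.633,-2.904
27.744,-2.427
27.836,-1.946
27.907,-1.463
27.959,-0.976
27.99,-0.489
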