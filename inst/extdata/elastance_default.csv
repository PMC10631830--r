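t_norm,e_norm
0,0
0.005,0.0086283761
0.01,0.021376864
0.015,0.036179966
0.02,0.05236774
0.025,0.069557869
0.03,0.087492807
0.035,0.10598365
0.04,0.12488466
0.045,0.14407966
0.05,0.16347399
0.055,0.18298935
0.06,0.2025603
0.065,0.2221317
0.07,0.24165695
0.075,0.26109647
0.08,0.28041666
0.085,0.29958898
0.09,0.31858925
0.095,0.337397
0.1,0.35599505
0.105,0.37436899
0.11,0.39250689
0.115,0.41039899
0.12,0.42803737
0.125,0.44541577
0.13,0.46252938
0.135,0.47937466
0.14,0.49594916
0.145,0.51225141
0.15,0.52828079
0.155,0.54403743
0.16,0.55952209
0.165,0.57473611
0.17,0.58968131
0.175,0.60435994
0.18,0.61877461
0.185,0.63292823
0.19,0.64682401
0.195,0.66046535
0.2,0.67385584
0.205,0.68699925
0.21,0.69989945
0.215,0.71256042
0.22,0.72498622
0.225,0.73718096
0.23,0.74914878
0.235,0.76089384
0.24,0.77242031
0.245,0.78373232
0.25,0.79483397
0.255,0.80572931
0.26,0.81642229
0.265,0.82691674
0.27,0.83721632
0.275,0.84732448
0.28,0.85724436
0.285,0.86697873
0.29,0.87652979
0.295,0.88589902
0.3,0.89508695
0.305,0.90409277
0.31,0.91291391
0.315,0.92154542
0.32,0.92997919
0.325,0.93820287
0.33,0.94619852
0.335,0.95394078
0.34,0.9613946
0.345,0.96851218
0.35,0.97522928
0.355,0.9814604
0.36,0.98709297
0.365,0.99198012
0.37,0.99593225
0.375,0.99870729
0.38,1
0.385,0.99943127
0.39,0.99653865
0.395,0.99077075
0.4,0.98148899
0.405,0.96798166
0.41,0.94949608
0.415,0.9252946
0.42,0.89473756
0.425,0.85739066
0.43,0.81314485
0.435,0.76232562
0.44,0.70576012
0.445,0.64477101
0.45,0.58108059
0.455,0.51663394
0.46,0.45337766
0.465,0.39304598
0.47,0.33700156
0.475,0.28615682
0.48,0.2409754
0.485,0.20153308
0.49,0.1676102
0.495,0.1387901
0.5,0.1145466
0.505,0.094312461
0.51,0.077527271
0.515,0.063667374
0.52,0.052261825
0.525,0.042898516
0.53,0.035223975
0.535,0.028939484
0.54,0.023795372
0.545,0.019584662
0.55,0.016136809
0.555,0.013311901
0.56,0.010995513
0.565,0.009094265
0.57,0.0075320516
0.575,0.0062468923
0.58,0.0051883229
0.585,0.0043152506
0.59,0.0035941998
0.595,0.0029978825
0.6,0.0025040358
0.605,0.0020944794
0.61,0.0017543505
0.615,0.0014714844
0.62,0.0012359125
0.625,0.0010394555
0.63,0.00087539313
0.635,0.00073819693
0.64,0.0006233125
0.645,0.00052698287
0.65,0.00044610462
0.655,0.00037811076
0.66,0.00032087508
0.665,0.0002726341
0.67,0.00023192324
0.675,0.00019752452
0.68,0.00016842373
0.685,0.00014377522
0.69,0.00012287295
0.695,0.00010512676
0.7,9.0042649e-05
0.705,7.7206641e-05
0.71,6.6271376e-05
0.715,5.694504e-05
0.72,4.8982186e-05
0.725,4.2176122e-05
0.73,3.635259e-05
0.735,3.1364501e-05
0.74,2.7087565e-05
0.745,2.3416631e-05
0.75,2.0262647e-05
0.755,1.7550109e-05
0.76,1.5214929e-05
0.765,1.3202656e-05
0.77,1.1466973e-05
0.775,9.9684424e-06
0.78,8.6734505e-06
0.785,7.5533171e-06
0.79,6.5835473e-06
0.795,5.7432002e-06
0.8,5.0143552e-06
0.805,4.3816618e-06
0.81,3.8319586e-06
0.815,3.3539501e-06
0.82,2.9379334e-06
0.825,2.5755658e-06
0.83,2.2596677e-06
0.835,1.984055e-06
0.84,1.7433959e-06
0.845,1.53309e-06
0.85,1.3491639e-06
0.855,1.1881833e-06
0.86,1.0471772e-06
0.865,9.2357296e-07
0.87,8.1514147e-07
0.875,7.1994941e-07
0.88,6.3631876e-07
0.885,5.6279189e-07
0.89,4.9810159e-07
0.895,4.4114539e-07
0.9,3.9096333e-07
0.905,3.4671897e-07
0.91,3.0768289e-07
0.915,2.7321853e-07
0.92,2.4276999e-07
0.925,2.1585143e-07
0.93,1.9203791e-07
0.935,1.7095754e-07
0.94,1.5228459e-07
0.945,1.3573356e-07
0.95,1.2105407e-07
0.955,1.0802634e-07
0.96,9.645737e-08
0.965,8.6177523e-08
0.97,7.7037619e-08
0.975,6.8906376e-08
0.98,6.1668185e-08
0.985,5.5221176e-08
0.99,4.9475528e-08
0.995,4.4351991e-08
1,3.9780601e-08
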