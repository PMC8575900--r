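gene,primary_direction,sirna_z_1,sirna_z_2,sirna_z_3
CAND001,up,4.338,-0.597,0.958
CAND002,down,-0.456,-0.186,-3.214
CAND003,up,4.285,0.621,2.612
CAND004,down,0.276,-1.177,0.35
CAND005,up,-0.888,-0.453,0.628
CAND006,down,0.851,0.883,0.058
CAND007,up,1.735,0.585,3.943
CAND008,down,-4.049,-2.889,-4.195
CAND009,up,0.213,1.584,0.422
CAND010,down,-0.254,0.008,0.548
CAND011,up,-1.668,-0.244,-1.047
CAND012,down,-2.348,-1.928,-3.973
CAND013,up,-0.669,0.512,-0.563
CAND014,down,-2.053,0.721,-2.458
CAND015,up,0.112,0.596,0.157
CAND016,down,-4.337,0.8,-1.37
CAND017,up,2.071,-0.527,3.135
CAND018,down,-1.82,-3.142,-3.911
CAND019,up,-0.256,-0.537,2.799
CAND020,down,-2.072,-2.216,-0.889
CAND021,up,2.657,3.41,1.568
CAND022,down,0.404,0.303,-0.828
CAND023,up,1.392,-0.087,-0.543
CAND024,down,-0.432,0.268,0.134
CAND025,up,0.619,0.141,0.29
CAND026,down,-0.423,-2.194,0.142
CAND027,up,0.184,0.238,2.873
CAND028,down,-0.051,-0.552,0.593
CAND029,up,4.107,0.41,3.323
CAND030,down,-1.964,-2.549,-2.805
CAND031,up,0.429,-0.217,3.9
CAND032,down,-0.455,-0.268,-3.594
CAND033,up,0.553,2.062,0.295
CAND034,down,-4.26,-3.647,-2.524
CAND035,up,-0.345,3.648,1.828
CAND036,down,0.349,-1.563,0.043
CAND037,up,1.164,-1.047,3.645
CAND038,down,-3.483,-4.089,-1.961
CAND039,up,1.165,0.52,0.796
CAND040,down,-0.33,-0.388,0.174
CAND041,up,0.414,4,-1.466
CAND042,down,-2.75,-0.893,-2.593
CAND043,up,0.934,-0.967,3.923
CAND044,down,1.24,-2.345,-0.134
CAND045,up,1.002,0.537,-1.554
CAND046,down,0.738,-3.137,-1.978
CAND047,up,-0.082,3.82,-0.847
CAND048,down,-0.666,-1.755,-0.203
CAND049,up,-0.334,0.35,4.336
CAND050,down,0.473,-2.606,-2.175
CAND051,up,2.176,-0.526,-0.412
CAND052,down,-0.547,0.982,-0.702
CAND053,up,-1.026,3.666,4.084
CAND054,down,-0.062,-4.238,0.896
CAND055,up,-0.456,-0.62,-0.086
CAND056,down,0.676,0.777,-0.589
CAND057,up,3.941,0.491,0.843
CAND058,down,0.757,-3.946,0.202
CAND059,up,0.919,0.471,-0.628
CAND060,down,-0.457,-0.673,-0.185
CAND061,up,0.557,-0.035,2.628
CAND062,down,-4.235,-1.744,-2.151
CAND063,up,-0.351,0.369,0.24
CAND064,down,-3.08,-0.237,-0.5
CAND065,up,0.185,-0.766,1
CAND066,down,-2.6,-1.949,-4.493
CAND067,up,-1.369,0.043,0.086
CAND068,down,-0.22,0.641,-0.123
CAND069,up,2.641,0.387,0.557
CAND070,down,0.464,-3.723,-4.309
CAND071,up,0.322,0.319,2.641
CAND072,down,0.103,0.14,0.088
CAND073,up,-0.413,-0.389,3.032
CAND074,down,-2.076,0.1,-0.406
CAND075,up,-0.865,0.121,3.791
CAND076,down,-1.679,-4.425,2.092
CAND077,up,-0.073,0.007,3.835
CAND078,down,-2.567,-1.428,-3.22
CAND079,up,0.939,0.957,-0.767
CAND080,down,-3.946,-4.424,-3.738
CAND081,up,-0.788,-0.89,-0.238
CAND082,down,0.124,0.218,-0.216
CAND083,up,0.719,2.22,0.774
CAND084,down,-2.202,0.944,0.729
CAND085,up,-0.118,0.093,-0.393
CAND086,down,-0.771,-0.685,-3.327
CAND087,up,-0.214,-0.731,-0.028
CAND088,down,-2.717,-2.394,-2.107
CAND089,up,-0.585,4.224,-1.305
CAND090,down,-2.741,-3.462,-3.631
CAND091,up,3.932,2.78,4.028
CAND092,down,0.415,1.295,-0.832
CAND093,up,-0.527,0.792,0.638
CAND094,down,-1.303,1.269,-0.126
CAND095,up,-0.864,-0.803,2.45
CAND096,down,0.62,-4.383,-2.386
CAND097,up,0.145,-0.86,-0.927
CAND098,down,0.769,-0.249,-0.71
CAND099,up,4.406,0.799,-0.661
CAND100,down,0.13,-2.429,0.519
CAND101,up,4.417,-0.115,3.991
CAND102,down,0.091,-2.869,-1.869
CAND103,up,-0.209,0.305,-0.005
CAND104,down,-3.388,0.636,-4.236
CAND105,up,3.521,0.33,1.773
CAND106,down,-1.825,-3.424,-4.419
CAND107,up,0.871,0.329,-0.132
CAND108,down,-0.225,-1.983,0.95
CAND109,up,0.036,-0.366,0.375
CAND110,down,-0.681,0.596,0.341
CAND111,up,0.481,3.673,-0.04
CAND112,down,-0.316,0.398,-0.691
CAND113,up,3.831,3.494,2.447
CAND114,down,0.49,0.175,0.121
CAND115,up,2.919,4.286,3.332
CAND116,down,0.11,1.177,-0.064
CAND117,up,0.201,0.83,4.153
CAND118,down,0.737,-0.296,-0.585
CAND119,up,-0.842,0.648,0.443
CAND120,down,0.448,-0.052,-2.798
CAND121,up,-0.58,4.438,-0.394
CAND122,down,-0.517,-0.097,-0.362
CAND123,up,1.789,-0.508,0.208
CAND124,down,0.259,1.878,-4.071
CAND125,up,-0.175,0.407,0.083
CAND126,down,0.488,-3.76,-2.173
CAND127,up,-0.438,-0.005,0.061
CAND128,down,-3.177,-2.133,-2.812
CAND129,up,-0.041,2.608,0.147
CAND130,down,-0.424,-4.108,-2.43
CAND131,up,3.649,-0.147,0.069
CAND132,down,0.813,-0.307,0.858
CAND133,up,0.599,0.408,0.573
CAND134,down,-0.924,0.582,-0.66
CAND135,up,0.486,0.272,-0.738
CAND136,down,0.235,-0.264,0.296
CAND137,up,2.642,4.378,0.619
CAND138,down,-0.305,-2.515,-3.714
CAND139,up,2.087,0.328,1.978
CAND140,down,-3.86,-1.647,-3.206
CAND141,up,0.151,-0.259,3.62
CAND142,down,0.38,-0.527,-0.271
CAND143,up,-0.341,0.353,1.11
CAND144,down,-4.184,-3.914,-2.072
CAND145,up,0.075,0.313,2.751
CAND146,down,-3.532,-0.092,-2.118
CAND147,up,2.931,3.077,4.027
CAND148,down,0.336,0.019,0.44
CAND149,up,-1.002,-0.718,1.154
CAND150,down,0.023,-4.392,-1.96
CAND151,up,0.185,0.337,0.649
CAND152,down,0.058,-0.382,0.569
CAND153,up,2.89,3.678,2.239
CAND154,down,-0.617,-2.737,-4.007
CAND155,up,2.545,3.746,4.355
CAND156,down,-3.523,-2.744,-1.968
CAND157,up,2.243,0.168,0.159
CAND158,down,-0.421,-2.822,-0.06
CAND159,up,2.367,4.189,2.748
CAND160,down,-2.239,0.35,-2.722
CAND161,up,3.32,3.43,2.197
CAND162,down,-2.266,0.886,-4.212
CAND163,up,-0.979,2.052,-0.262
CAND164,down,0.38,-2.375,-0.298
CAND165,up,1.948,4.256,3.903
CAND166,down,-0.974,0.686,0.527
CAND167,up,0.594,3.528,-0.097
CAND168,down,-0.268,0.204,-0.079
CAND169,up,0.391,2.614,0.008
CAND170,down,-3.026,-2.908,-0.429
CAND171,up,0.171,0.557,0.248
CAND172,down,-1.794,-3.574,-3.583
CAND173,up,-0.087,0.493,-0.059
CAND174,down,-2.786,-0.337,-0.751
CAND175,up,0.243,1.68,3.752
CAND176,down,-0.035,-2.788,-2.286
CAND177,up,3.323,0.839,-0.268
CAND178,down,0.262,0.827,0.223
CAND179,up,1.324,2.427,-0.034
CAND180,down,-2.975,0.425,-0.145
CAND181,up,-1.132,0.247,-0.668
CAND182,down,-3.199,-0.493,-4.142
CAND183,up,-0.761,4.294,-1.012
CAND184,down,-2.03,-4.064,-1.592
CAND185,up,1.787,-0.099,0.439
CAND186,down,-0.88,-0.029,-1.135
CAND187,up,1.802,0.811,0.901
CAND188,down,-0.239,-0.632,-2.361
CAND189,up,0.597,-0.921,4.38
CAND190,down,-1.641,-2.625,-3.631
CAND191,up,1.89,2.27,3.647
CAND192,down,-0.313,-0.028,0.222
CAND193,up,4.243,-0.035,0.011
CAND194,down,-1.456,-0.904,-0.421
CAND195,up,-0.614,-0.318,4.466
CAND196,down,-0.989,-0.348,-0.292
CAND197,up,0.301,0.059,3.588
CAND198,down,0.184,0.022,-2.245
CAND199,up,2.657,0.473,-0.343
CAND200,down,0.418,-3.794,-0.453
CAND201,up,4.039,0.296,1.06
CAND202,down,-3.674,-3.852,-4.037
CAND203,up,2.185,-1.956,0.876
CAND204,down,-2.589,-3.699,-0.194
CAND205,up,-0.936,0.868,0.705
CAND206,down,0.546,-3.517,0.505
CAND207,up,0.93,-0.101,3.408
CAND208,down,-0.038,0.989,-0.277
CAND209,up,3.64,-0.135,4.098
CAND210,down,0.607,0.835,-3.017
CAND211,up,0.062,-0.21,-0.753
CAND212,down,-0.425,-0.435,-1.957
CAND213,up,0.329,-0.625,-0.779
CAND214,down,-4.479,-0.201,0.294
CAND215,up,4.088,0.503,1.913
CAND216,down,-0.092,-4.466,0.385
CAND217,up,-0.139,-0.601,-0.748
CAND218,down,-0.511,-0.089,-0.59
CAND219,up,0.068,3.206,0.979
CAND220,down,-1.62,-2.359,-3.119
CAND221,up,0.226,0.118,3.378
CAND222,down,0.617,-1.038,-0.143
CAND223,up,1.94,1.988,3.034
CAND224,down,-0.517,0.545,0.296
CAND225,up,2.98,0.061,-0.767
CAND226,down,0.658,-0.278,0.162
CAND227,up,-1.406,-0.271,-0.63
CAND228,down,-0.612,0.506,-0.073
CAND229,up,4.495,0.58,0.551
CAND230,down,-2.806,-0.096,-4.009
CAND231,up,1.806,0.67,-0.411
CAND232,down,-0.432,0.07,0.812
CAND233,up,-0.815,-0.07,-0.781
CAND234,down,0.196,0.622,-0.682
CAND235,up,0.868,1.978,-0.333
CAND236,down,0.749,-0.382,0.257
CAND237,up,-0.253,-0.234,0.448
CAND238,down,-3.446,-4.327,-4.426
CAND239,up,-0.069,-0.351,0.111
CAND240,down,0.755,-1.694,0.006
CAND241,up,2.342,3.064,3.17
CAND242,down,-2.176,-1.061,-0.954
CAND243,up,0.318,2.143,0.299
CAND244,down,0.211,-4.413,-0.066
CAND245,up,3.979,0.023,-0.234
CAND246,down,-0.385,0.718,0.774
CAND247,up,0.765,-0.104,1.227
CAND248,down,0.831,-4.026,0.92
CAND249,up,0.532,0.124,0.825
CAND250,down,0.119,-0.121,-2.134
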