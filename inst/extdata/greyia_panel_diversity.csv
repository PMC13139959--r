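assay,species,n,maf,h_o,h_s,pic,n_gsu,h_o_gsu,h_s_gsu,pic_gsu,n_gra,h_o_gra,h_s_gra,pic_gra,n_gfl,h_o_gfl,h_s_gfl,pic_gfl
Greyia_3RAD_D1_16417.28,GFL,73,0.445,0.836,0.497,0.372,43,0.953,0.505,0.374,20,1.000,0.513,0.375,10,0.00,0.00,0.000
Greyia_3RAD_D1_17901.48,GSU,72,0.194,0.306,0.315,0.264,42,0.476,0.433,0.336,20,0.050,0.050,0.048,10,0.10,0.10,0.090
Greyia_3RAD_D1_20015.167,GRA,73,0.486,0.151,0.503,0.375,43,0.256,0.291,0.247,20,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_3RAD_D1_16438.7,GFL,73,0.144,0.014,0.248,0.216,43,0.023,0.023,0.023,20,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_3RAD_D1_18402.102,GSU,73,0.233,0.055,0.360,0.293,43,0.000,0.000,0.000,20,0.200,0.262,0.222,10,0.00,0.00,0.000
Greyia_3RAD_D1_20179.46,GRA,73,0.473,0.616,0.502,0.374,43,0.721,0.479,0.361,20,0.450,0.358,0.288,10,0.50,0.39,0.305
Greyia_3RAD_D1_16444.229,GRA,73,0.103,0.151,0.186,0.167,43,0.000,0.000,0.000,20,0.550,0.481,0.359,10,0.00,0.00,0.000
Greyia_3RAD_D1_19009.73,GFL,73,0.226,0.178,0.352,0.289,43,0.302,0.479,0.361,20,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_BarSNP_its2_01,GFL,73,0.240,0.342,0.367,0.298,43,0.279,0.243,0.211,20,0.450,0.358,0.288,10,0.40,0.44,0.332
Greyia_3RAD_D1_16938.173,GRA,73,0.425,0.822,0.492,0.369,43,0.814,0.488,0.366,20,0.950,0.512,0.374,10,0.60,0.44,0.332
Greyia_3RAD_D1_19082.71,GFL,73,0.493,0.521,0.503,0.375,43,0.372,0.492,0.368,20,0.650,0.450,0.342,10,0.90,0.52,0.372
Greyia_BarSNP_its2_02,GSU,73,0.308,0.507,0.429,0.336,43,0.814,0.506,0.375,20,0.100,0.097,0.090,10,0.00,0.00,0.000
Greyia_3RAD_D1_16946.51,GSU,72,0.493,0.097,0.503,0.375,43,0.163,0.260,0.224,19,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_3RAD_D1_19227.91,GFL,73,0.144,0.014,0.248,0.216,43,0.023,0.023,0.023,20,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_BarSNP_its2_03,GFL,73,0.432,0.863,0.494,0.370,43,1.000,0.506,0.375,20,1.000,0.513,0.375,10,0.00,0.00,0.000
Greyia_3RAD_D1_17188.43,GSU,72,0.243,0.042,0.371,0.300,42,0.000,0.000,0.000,20,0.150,0.224,0.195,10,0.00,0.00,0.000
Greyia_3RAD_D1_19287.52,GSU,68,0.404,0.426,0.485,0.366,38,0.658,0.464,0.353,20,0.200,0.262,0.222,10,0.00,0.00,0.000
Greyia_BarSNP_matK_01,GFL,73,0.144,0.123,0.248,0.216,43,0.093,0.131,0.121,20,0.000,0.000,0.000,10,0.50,0.39,0.305
Greyia_3RAD_D1_17357.154,GRA,70,0.407,0.414,0.486,0.366,42,0.262,0.503,0.374,19,0.947,0.512,0.374,9,0.00,0.00,0.000
Greyia_3RAD_D1_19922.176,GRA,72,0.292,0.111,0.416,0.328,43,0.186,0.506,0.375,19,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_BarSNP_trnLH_01,GSU,72,0.236,0.028,0.363,0.296,42,0.048,0.488,0.366,20,0.000,0.000,0.000,10,0.00,0.00,0.000
Greyia_3RAD_D1_17371.56,GSU,73,0.199,0.397,0.321,0.268,43,0.047,0.046,0.044,20,0.850,0.501,0.369,10,1.00,0.53,0.375
Greyia_3RAD_D1_19983.195,GFL,67,0.224,0.239,0.350,0.287,40,0.350,0.292,0.247,19,0.053,0.053,0.050,8,0.125,0.125,0.110
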