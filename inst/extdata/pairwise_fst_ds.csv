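population,abrolhos,gbr,cook,fiji,frpoly,indonesia,iran,png,solomon,taiwan,tan_mafia,tan_mtwara,tonga,vietnam
abrolhos,0,0.056,0.095,0.068,0.082,0.053,0.264,0.056,0.057,0.053,0.236,0.238,0.069,0.051
gbr,0.1311,0,0.033,0.009,0.021,0.009,0.256,0.005,0.005,0.009,0.234,0.236,0.011,0.008
cook,0.2173,0.0816,0,0.023,0.020,0.044,0.306,0.035,0.035,0.044,0.289,0.291,0.027,0.043
fiji,0.1526,0.0194,0.0537,0,0.011,0.018,0.273,0.011,0.010,0.017,0.253,0.255,0.006,0.016
frpoly,0.1892,0.0490,0.0502,0.0221,0,0.031,0.292,0.022,0.021,0.030,0.275,0.277,0.014,0.028
indonesia,0.1209,0.0211,0.1084,0.0459,0.0759,0,0.243,0.008,0.009,0.006,0.217,0.219,0.020,0.006
iran,0.4177,0.4145,0.4684,0.3903,0.4438,0.3711,0,0.255,0.257,0.241,0.071,0.074,0.276,0.239
png,0.1297,0.0079,0.0862,0.0227,0.0532,0.0166,0.4086,0,0.005,0.008,0.232,0.233,0.013,0.007
solomon,0.1297,0.0071,0.0835,0.0248,0.0499,0.0208,0.38462,0.0056,0,0.008,0.234,0.237,0.012,0.008
taiwan,0.1196,0.0172,0.1090,0.0375,0.0739,0.0100,0.41411,0.0148,0.0128,0,0.217,0.218,0.020,0.006
tan_mafia,0.3508,0.3494,0.4185,0.3374,0.3951,0.3038,0.24438,0.3444,0.3236,0.3394,0,0.013,0.257,0.214
tan_mtwara,0.3402,0.3323,0.4043,0.3235,0.3804,0.2894,0.2534,0.3280,0.3084,0.3200,0.0069,0,0.259,0.216
tonga,0.1607,0.0235,0.0628,0.0099,0.0294,0.0494,0.44413,0.0279,0.0254,0.0443,0.3846,0.3644,0,0.019
vietnam,0.1128,0.0185,0.1062,0.0407,0.0732,0.0124,0.37119,0.0161,0.0174,0.0088,0.3043,0.2906,0.0469,0
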