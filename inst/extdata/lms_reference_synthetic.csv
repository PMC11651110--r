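"measure","sex","age_months","L","M","S"
"bmi","F",36,-1.6,15.38,0.085
"bmi","F",48,-1.58,15.32,0.087
"bmi","F",60,-1.56,15.3,0.089
"bmi","F",72,-1.54,15.32,0.091
"bmi","F",84,-1.52,15.38,0.093
"bmi","F",96,-1.5,15.48,0.095
"bmi","F",108,-1.48,15.62,0.097
"bmi","F",120,-1.46,15.8,0.099
"bmi","F",132,-1.44,16.02,0.101
"bmi","F",144,-1.42,16.28,0.103
"bmi","F",156,-1.4,16.58,0.105
"bmi","F",168,-1.38,16.92,0.107
"bmi","F",180,-1.36,17.3,0.109
"height","F",36,1,0.95,0.04
"height","F",48,1,0.996,0.0405
"height","F",60,1,1.042,0.041
"height","F",72,1,1.088,0.0415
"height","F",84,1,1.134,0.042
"height","F",96,1,1.18,0.0425
"height","F",108,1,1.226,0.043
"height","F",120,1,1.272,0.0435
"height","F",132,1,1.318,0.044
"height","F",144,1,1.364,0.0445
"height","F",156,1,1.41,0.045
"height","F",168,1,1.456,0.0455
"height","F",180,1,1.502,0.046
"weight","F",36,-0.3,14.5,0.11
"weight","F",48,-0.31,15.55,0.113
"weight","F",60,-0.32,16.6,0.116
"weight","F",72,-0.33,17.65,0.119
"weight","F",84,-0.34,18.7,0.122
"weight","F",96,-0.35,19.75,0.125
"weight","F",108,-0.36,20.8,0.128
"weight","F",120,-0.37,21.85,0.131
"weight","F",132,-0.38,22.9,0.134
"weight","F",144,-0.39,23.95,0.137
"weight","F",156,-0.4,25,0.14
"weight","F",168,-0.41,26.05,0.143
"weight","F",180,-0.42,27.1,0.146
"bmi","M",36,-1.6,15.58,0.085
"bmi","M",48,-1.58,15.52,0.087
"bmi","M",60,-1.56,15.5,0.089
"bmi","M",72,-1.54,15.52,0.091
"bmi","M",84,-1.52,15.58,0.093
"bmi","M",96,-1.5,15.68,0.095
"bmi","M",108,-1.48,15.82,0.097
"bmi","M",120,-1.46,16,0.099
"bmi","M",132,-1.44,16.22,0.101
"bmi","M",144,-1.42,16.48,0.103
"bmi","M",156,-1.4,16.78,0.105
"bmi","M",168,-1.38,17.12,0.107
"bmi","M",180,-1.36,17.5,0.109
"height","M",36,1,0.951,0.04
"height","M",48,1,0.997,0.0405
"height","M",60,1,1.043,0.041
"height","M",72,1,1.089,0.0415
"height","M",84,1,1.135,0.042
"height","M",96,1,1.181,0.0425
"height","M",108,1,1.227,0.043
"height","M",120,1,1.273,0.0435
"height","M",132,1,1.319,0.044
"height","M",144,1,1.365,0.0445
"height","M",156,1,1.411,0.045
"height","M",168,1,1.457,0.0455
"height","M",180,1,1.503,0.046
"weight","M",36,-0.3,14.7,0.11
"weight","M",48,-0.31,15.75,0.113
"weight","M",60,-0.32,16.8,0.116
"weight","M",72,-0.33,17.85,0.119
"weight","M",84,-0.34,18.9,0.122
"weight","M",96,-0.35,19.95,0.125
"weight","M",108,-0.36,21,0.128
"weight","M",120,-0.37,22.05,0.131
"weight","M",132,-0.38,23.1,0.134
"weight","M",144,-0.39,24.15,0.137
"weight","M",156,-0.4,25.2,0.14
"weight","M",168,-0.41,26.25,0.143
"weight","M",180,-0.42,27.3,0.146
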