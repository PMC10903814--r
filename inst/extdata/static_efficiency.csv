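region,2016,2017,2018,2019,2020,mean
Haikou City,1.248,1.264,1.223,1.112,1.134,1.196
Sanya City,0.652,1.043,1.001,0.559,0.642,0.779
Wuzhishan City,1.003,1.053,1.038,1.064,1.081,1.047
Wenchang City,0.774,0.806,1.013,1.023,0.595,0.842
Qionghai City,1.031,1.058,1.098,1.114,0.898,1.040
Wanning City,1.087,1.033,1.016,1.026,0.590,0.950
Ding'an County,1.061,1.079,1.014,1.043,0.740,0.988
Tunchang County,1.119,1.107,1.098,1.020,1.109,1.090
Chengmai County,0.738,1.017,1.054,0.667,1.304,0.956
Danzhou City,1.035,1.030,0.827,0.755,1.042,0.938
Dongfang City,0.845,1.005,0.861,0.852,0.652,0.843
Baoting County,1.156,1.098,1.138,1.137,1.170,1.140
Lingshui County,1.115,1.069,1.164,1.115,0.657,1.024
Baisha County,0.650,0.852,0.749,1.032,0.534,0.764
Changjiang County,0.899,1.041,1.028,1.082,1.101,1.030
Mean,0.961,1.037,1.021,0.973,0.883,0.975
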