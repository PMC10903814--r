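region,effch,tech,pech,sech,tfp
Haikou City,0.977,1.006,1.046,0.980,0.981
Sanya City,1.066,0.907,1.028,1.021,0.962
Wuzhishan City,1.019,0.971,1.017,1.002,0.991
Wenchang City,0.972,0.902,0.963,1.001,0.868
Qionghai City,0.971,0.926,0.992,0.977,0.909
Wanning City,0.880,0.865,0.896,0.975,0.758
Ding'an County,0.924,0.944,0.925,0.999,0.874
Tunchang County,0.999,0.914,1.001,0.999,0.911
Chengmai County,1.251,0.976,1.114,1.103,1.225
Danzhou City,1.023,0.913,1.001,1.019,0.900
Dongfang City,0.950,0.877,0.916,1.048,0.830
Baoting County,1.004,0.964,1.038,0.992,0.968
Lingshui County,0.899,0.963,0.901,1.000,0.871
Baisha County,1.021,0.952,1.045,0.966,0.971
Changjiang County,1.054,0.942,1.059,0.995,0.993
Mean,1.001,0.935,0.996,1.005,0.934
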