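interval,effch,tech,pech,sech,tfp
2016-2017,1.108,0.993,1.086,1.030,1.099
2017-2018,0.988,0.950,1.002,0.987,0.936
2018-2019,0.961,0.974,0.977,0.985,0.935
2019-2020,0.946,0.822,0.919,1.019,0.766
Mean,1.001,0.935,0.996,1.005,0.934
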