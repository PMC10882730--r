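parameter,rr,lower,upper
intercept,0.037,0.035,0.040
age65_74,1.017,1.008,1.026
age75plus,1.009,1.001,1.016
male,1.016,1.002,1.028
distance_km,1.005,1.001,1.009
imd,0.998,0.996,0.999
year2013,0.965,0.878,1.054
year2014,0.991,0.909,1.078
year2015,1.030,0.950,1.128
year2016,1.091,1.000,1.191
year2017,1.049,0.963,1.149
year2018,0.975,0.894,1.064
year2019,0.961,0.880,1.049
mbrn,1.001,1.000,1.003
year2013:mbrn,0.998,0.996,1.000
year2014:mbrn,0.999,0.997,1.001
year2015:mbrn,0.998,0.996,1.000
year2016:mbrn,0.999,0.997,1.001
year2017:mbrn,0.999,0.997,1.001
year2018:mbrn,0.996,0.994,0.998
year2019:mbrn,0.995,0.993,0.997
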