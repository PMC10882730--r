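year,total
2012,968
2013,974
2014,1039
2015,1120
2016,1218
2017,1204
2018,1165
2019,1209
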