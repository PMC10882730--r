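year,raw,adjusted
2012,22803,26293
2013,23747,26962
2014,24876,27820
2015,25936,28477
2016,27082,29305
2017,28234,29975
2018,29262,30631
2019,30902,31715
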