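site_id,period,individuals_all,richness_all,individuals_eleven,richness_eleven
1,historical,161,10,147,8
2,historical,81,7,73,5
3,historical,134,6,133,5
4,historical,70,7,67,4
5,historical,65,5,65,5
6,historical,107,7,105,6
7,historical,43,5,40,4
8,historical,64,2,64,2
1,modern,193,12,186,9
2,modern,179,9,176,7
3,modern,73,7,72,6
4,modern,43,5,43,5
5,modern,39,5,39,5
6,modern,100,6,99,5
7,modern,37,5,36,4
8,modern,46,2,46,2
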