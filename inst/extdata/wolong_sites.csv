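site_id,elevation_m,vegetation,trap_nights_hist,trap_nights_mod
1,1550,EB,2430,2300
2,1800,EDMB,1200,1200
3,1930,EDMB,1200,1100
4,2200,CBM,1220,1100
5,2500,CBM,1200,1100
6,2800,CF,1250,1100
7,3050,CF,1250,1100
8,3500,SSM,1680,1500
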