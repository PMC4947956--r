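dose_Gy,n_cells,n_dead
15,5000,600
20,6200,850
25,5500,800
30,5900,2000
35,6500,2400
40,6000,2600
45,5700,2800
50,5500,3200
55,5800,3700
60,6000,4100
65,5600,4300
70,6700,5600
75,6300,5500
80,6100,5600
85,6800,6400
90,7000,7000
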