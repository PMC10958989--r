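age_lo,age_hi,female,weight
50,54,0,1790
50,54,1,1850
55,59,0,1590
55,59,1,1650
60,64,0,1780
60,64,1,1850
65,69,0,1370
65,69,1,1440
70,74,0,1110
70,74,1,1220
75,79,0,870
75,79,1,1030
80,84,0,610
80,84,1,830
85,89,0,340
85,89,1,570
90,120,0,130
90,120,1,320
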