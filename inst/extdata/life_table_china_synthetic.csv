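"age","annual_mortality_probability"
40,0.00192857580694894
41,0.00207084654009448
42,0.00222727239931797
43,0.0023992591737142
44,0.00258835172899086
45,0.00279624765416453
46,0.00302481222375051
47,0.00327609479728419
48,0.00355234678823257
49,0.00385604134519679
50,0.00418989489975441
51,0.00455689074730126
52,0.00496030483977306
53,0.00540373398205563
54,0.00589112663711799
55,0.00642681655823629
56,0.00701555947989951
57,0.00766257311179319
58,0.00837358069226379
59,0.00915485836838026
60,0.0100132866785098
61,0.0109564064194492
62,0.0119924791826315
63,0.0131305528415874
64,0.0143805322642396
65,0.0157532555069756
66,0.0172605757206581
67,0.0189154489592132
68,0.0207320280261023
69,0.0227257624191588
70,0.0249135043355743
71,0.0273136205711182
72,0.0299461099849067
73,0.0328327259961799
74,0.0359971033244629
75,0.0394648878698654
76,0.0432638682455572
77,0.0474241070078244
78,0.0519780690675057
79,0.0569607440959271
80,0.0624097589437569
81,0.0683654751572518
82,0.0748710655883337
83,0.0819725628394657
84,0.0897188708511106
85,0.0981617293234973
86,0.107355618868398
87,0.117357592825291
88,0.128227019581034
89,0.140025217056982
90,0.152814958856894
91,0.166659829526485
92,0.181623404634751
93,0.197768230183013
94,0.215154575488786
95,0.233838934572195
96,0.253872253682121
97,0.275297867526603
98,0.298149134701982
99,0.322446774509897
100,0.348195923610828
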