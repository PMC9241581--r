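"age","annual_mortality_probability"
40,0.00170628437543874
41,0.00181982206174303
42,0.00194403728419545
43,0.00207993267666462
44,0.0022286047210528
45,0.00239125247231908
46,0.00256918708294507
47,0.00276384219776848
48,0.00297678529593015
49,0.0032097300628916
50,0.00346454988206946
51,0.0037432925426113
52,0.004048196267186
53,0.00438170717136843
54,0.00474649827422546
55,0.00514549018801636
56,0.00558187362343554
57,0.00605913385546875
58,0.00658107730357227
59,0.00715186038838822
60,0.00777602083536155
61,0.00845851160319433
62,0.00920473762174523
63,0.0100205955293784
64,0.0109125166034149
65,0.011887513078661
66,0.0129532280472843
67,0.0141179891277283
68,0.0153908660798702
69,0.0167817325270093
70,0.0183013319210568
71,0.0199613478537225
72,0.0217744787715184
73,0.0237545170935584
74,0.0259164326556031
75,0.0282764603082428
76,0.0308521913776815
77,0.0336626685498533
78,0.0367284835575237
79,0.0400718768298368
80,0.0437168379980879
81,0.0476892058331593
82,0.0520167658113099
83,0.0567293430574796
84,0.0618588878902168
85,0.0674395505808616
86,0.0735077412330797
87,0.0801021698794584
88,0.0872638609734823
89,0.0950361354243929
90,0.103464552179971
91,0.112596800114989
92,0.122482529646329
93,0.133173112096285
94,0.144721313405481
95,0.157180867417714
96,0.170605932707282
97,0.185050415912199
98,0.200567143928029
99,0.21720686730446
100,0.235017078016976
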