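age	qx
0	0.000507870989846615
1	0.000508800741543802
2	0.00050983860195275
3	0.000510997141494496
4	0.000512290392192472
5	0.00051373401760979
6	0.000515345502542064
7	0.000517144364764022
8	0.000519152391389888
9	0.000521393902712108
10	0.000523896046708106
11	0.000526689127781088
12	0.000529806973712188
13	0.000533287345264033
14	0.00053717239338924
15	0.000541509169576293
16	0.000546350195503309
17	0.000551754098887636
18	0.000557786323218679
19	0.000564519919951434
20	0.000572036432733514
21	0.000580426884346674
22	0.000589792878281536
23	0.000600247828243972
24	0.00061191833042884
25	0.000624945695115398
26	0.000639487656048043
27	0.0006557202782006
28	0.000673840086898636
29	0.000694066443922003
30	0.000716644199160732
31	0.000741846649685241
32	0.000769978841749341
33	0.000801381255323919
34	0.00083643391528776
35	0.000875560978455092
36	0.000919235851222666
37	0.000967986898863127
38	0.00102240381441598
39	0.00108314472282467
40	0.00115094410450689
41	0.00122662163201182
42	0.00131109202391
43	0.00140537603167357
44	0.00151061268814279
45	0.00162807296036249
46	0.00175917496520595
47	0.00190550092343778
48	0.00206881604679865
49	0.00225108957347286
50	0.00245451819003706
51	0.00268155210281196
52	0.00293492404854767
53	0.00321768156365554
54	0.00353322286281299
55	0.00388533671171876
56	0.00427824671501376
57	0.00471666047878294
58	0.0052058241473677
59	0.00575158285605926
60	0.00636044768405231
61	0.00703966973497827
62	0.00779732201431604
63	0.00864238981245458
64	0.00958487033717303
65	0.0106358823671735
66	0.0118077867156633
67	0.0131143182954833
68	0.0145707305594014
69	0.0161939530439644
70	0.0180027626640067
71	0.0200179692767255
72	0.0222626158457552
73	0.0247621932705081
74	0.0275448695842384
75	0.0306417327417131
76	0.0340870455852083
77	0.0379185107615955
78	0.0421775423235182
79	0.0469095394378278
80	0.0521641559920125
81	0.0579955578759345
82	0.0644626572586621
83	0.0716293102130509
84	0.0795644604999187
85	0.0883422081527482
86	0.0980417766631534
87	0.108747347047327
88	0.120547720913348
89	0.13353576796141
90	0.147807606353441
91	0.163461457454293
92	0.180596110144229
93	0.199308925065619
94	0.219693306961263
95	0.241835575254655
96	0.265811171242336
97	0.291680157236449
98	0.31948199170105
99	0.34922960820344
100	1
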