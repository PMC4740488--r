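age	qx_male	qx_female
0	0.000229973552027696	0.000229973552027696
1	0.000232972857608149	0.000232972857608149
2	0.000236272083353972	0.000236272083353972
3	0.000239901219099448	0.000239901219099448
4	0.000243893253203731	0.000243893253203731
5	0.000248284472307625	0.000248284472307625
6	0.000253114791044839	0.000253114791044839
7	0.00025842811470056	0.00025842811470056
8	0.000264272738106475	0.000264272738106475
9	0.000270701784388372	0.000270701784388372
10	0.000277773687546556	0.000277773687546556
11	0.000285552723241378	0.000285552723241378
12	0.00029410959259335	0.00029410959259335
13	0.000303522064287187	0.000303522064287187
14	0.000313875680793552	0.000313875680793552
15	0.000325264535100067	0.000325264535100067
16	0.000337792124979863	0.000337792124979863
17	0.000351572292522362	0.000351572292522362
18	0.000366730257418735	0.000366730257418735
19	0.000383403753334233	0.000383403753334233
20	0.000401744277627292	0.000401744277627292
21	0.000421918465688065	0.000421918465688065
22	0.000444109602283582	0.000444109602283582
23	0.000468519283523428	0.000468519283523428
24	0.000495369244395305	0.000495369244395305
25	0.00052490336830191	0.00052490336830191
26	0.000557389896635341	0.000557389896635341
27	0.000593123858205646	0.000593123858205646
28	0.000632429740274221	0.000632429740274221
29	0.000675664425073053	0.000675664425073053
30	0.000723220418018644	0.000723220418018644
31	0.000775529396380814	0.000775529396380814
32	0.000833066109952596	0.000833066109952596
33	0.000896352668324552	0.000896352668324552
34	0.000965963252693713	0.000965963252693713
35	0.00104252929378512	0.00104252929378512
36	0.00112674516143185	0.00112674516143185
37	0.00121937441569664	0.00121937441569664
38	0.0013212566741333	0.0013212566741333
39	0.00143331515492395	0.00143331515492395
40	0.00155656496120571	0.00155656496120571
41	0.00169212217795978	0.00169212217795978
42	0.00184121385939573	0.00184121385939573
43	0.00200518899186597	0.00200518899186597
44	0.00218553052500858	0.00218553052500858
45	0.00238386857207351	0.00238386857207351
46	0.00260199488926072	0.00260199488926072
47	0.00284187875340303	0.00284187875340303
48	0.00310568436747494	0.00310568436747494
49	0.0033957899342032	0.0033957899342032
50	0.0037148085494858	0.0037148085494858
51	0.00406561107935521	0.00406561107935521
52	0.00445135119681606	0.00445135119681606
53	0.00487549276795674	0.00487549276795674
54	0.00534183979017511	0.00534183979017511
55	0.00585456909901461	0.00585456909901461
56	0.00641826607377693	0.00641826607377693
57	0.00703796358548447	0.00703796358548447
58	0.00771918444355879	0.00771918444355879
59	0.00846798760931533	0.00846798760931533
60	0.00929101845447489	0.00929101845447489
61	0.0101955633506389	0.0101955633506389
62	0.0111896088801936	0.0111896088801936
63	0.0122819059592741	0.0122819059592741
64	0.013482039157899	0.013482039157899
65	0.0148005014895106	0.0148005014895106
66	0.0162487749199223	0.0162487749199223
67	0.0178394168116436	0.0178394168116436
68	0.0195861524708048	0.0195861524708048
69	0.021503973896925	0.021503973896925
70	0.0236092447464061	0.0236092447464061
71	0.025919811403927	0.025919811403927
72	0.0284551199060888	0.0284551199060888
73	0.03123633827189	0.03123633827189
74	0.03428648355705	0.03428648355705
75	0.0376305526547679	0.0376305526547679
76	0.0412956555038695	0.0412956555038695
77	0.0453111489248347	0.0453111489248347
78	0.0497087687719587	0.0497087687719587
79	0.0545227574517576	0.0545227574517576
80	0.0597899830985794	0.0597899830985794
81	0.0655500458025285	0.0655500458025285
82	0.0718453652366421	0.0718453652366421
83	0.078721242815161	0.078721242815161
84	0.0862258901205311	0.0862258901205311
85	0.0944104137555986	0.0944104137555986
86	0.103328745008478	0.103328745008478
87	0.113037500770395	0.113037500770395
88	0.123595760046108	0.123595760046108
89	0.135064738187902	0.135064738187902
90	0.147507338741076	0.147507338741076
91	0.160987560622002	0.160987560622002
92	0.175569736416537	0.175569736416537
93	0.191317576103487	0.191317576103487
94	0.208292989762719	0.208292989762719
95	0.226554663192388	0.226554663192388
96	0.246156362301945	0.246156362301945
97	0.267144946236543	0.267144946236543
98	0.289558076096065	0.289558076096065
99	0.313421616599246	0.313421616599246
100	0.338746742929088	0.338746742929088
101	0.365526785097323	0.365526785097323
102	0.393733868203474	0.393733868203474
103	0.423315439418145	0.423315439418145
104	0.454190811431026	0.454190811431026
105	0.486247896811354	0.486247896811354
106	0.519340356550277	0.519340356550277
107	0.55328543592584	0.55328543592584
108	0.587862806939746	0.587862806939746
109	0.622814772067769	0.622814772067769
110	1	1
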