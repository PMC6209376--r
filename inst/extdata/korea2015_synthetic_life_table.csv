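age,qx
0,0.000229973552027696
1,0.000232798126820977
2,0.000235888694779529
3,0.000239270303815986
4,0.000242970360356698
5,0.000247018851383118
6,0.000251448587369141
7,0.000256295468081591
8,0.000261598773391603
9,0.000267401481449436
10,0.000273750616795021
11,0.000280697631216631
12,0.000288298820437904
13,0.000296615779994625
14,0.000305715903987536
15,0.000315672930733313
16,0.000326567539718936
17,0.000338488004673732
18,0.000351530908023423
19,0.000365801922484921
20,0.000381416666094481
21,0.00039850163755295
22,0.000417195239408863
23,0.000437648897305687
24,0.000460028284280267
25,0.000484514659935154
26,0.000511306335223005
27,0.000540620274568915
28,0.000572693848148176
29,0.000607786748315298
30,0.00064618308547415
31,0.000688193680081661
32,0.000734158569012378
33,0.000784449746177418
34,0.000839474159107456
35,0.000899676985187114
36,0.000965545213371555
37,0.00103761155955551
38,0.0011164587462954
39,0.00120272418033596
40,0.00129710506437608
41,0.0014003639827338
42,0.00151333500406581
43,0.001636930348071
44,0.00177214766717904
45,0.00192007799861627
46,0.00208191444696171
47,0.00225896166237327
48,0.00245264618509922
49,0.00266452773268888
50,0.00289631151250791
51,0.00314986164873121
52,0.00342721581994465
53,0.00373060121081636
54,0.00406245188898691
55,0.00442542772633792
56,0.00482243499209556
57,0.00525664875373011
58,0.00573153723025321
59,0.00625088825116427
60,0.0068188379828098
61,0.00743990209210765
62,0.00811900952519751
63,0.00886153908532006
64,0.00967335899971178
65,0.0105608696690661
66,0.0115310497945968
67,0.0125915060762281
68,0.0137505266701142
69,0.0150171385835239
70,0.0164011691688991
71,0.0179133118551706
72,0.0195651962214355
73,0.0213694624738444
74,0.023339840328585
75,0.0254912322293683
76,0.0278398007335179
77,0.0304030597828276
78,0.0331999694293827
79,0.0362510334075171
80,0.0395783987253168
81,0.0432059561861796
82,0.0471594404358335
83,0.0514665277551384
84,0.0561569293756374
85,0.0612624775744357
86,0.066817201198667
87,0.0728573865689027
88,0.0794216189074882
89,0.0865507985256868
90,0.0942881249790508
91,0.102679041264097
92,0.11177112888757
93,0.121613943307053
94,0.132258777844549
95,0.143758342753807
96,0.156166344738111
97,0.169536950952686
98,0.183924120500094
99,0.199380785789568
100,1
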