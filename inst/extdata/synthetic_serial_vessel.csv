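# label=synthetic-serial-demo
s_mm,r_mm
0,1.5839214747771622
0.5,1.5820841082653194
1,1.5802467417534767
1.5,1.5784093752416339
2,1.5765720087297914
2.5,1.5747346422179487
3,1.5728972757061059
3.5,1.5710599091942632
4,1.5692225426824205
4.5,1.5673851761705777
5,1.5655478096587352
5.5,1.5637104431468924
6,1.5618730766350497
6.5,1.560035710123207
7,1.5581983436113642
7.5,1.5563609770995217
8,1.554523610587679
8.5,1.5526862440758364
9,1.5508488775639937
9.5,1.549011511052151
10,1.5471741445403082
10.5,1.5453367780284655
11,1.5434994115166227
11.5,1.5416620450047802
12,1.5398246784929375
12.5,1.5379873119810947
13,1.536149945469252
13.5,1.5343125789574092
14,1.5324752124455665
14.5,1.530637845933724
15,1.5288004794218812
15.5,1.5269631129100385
16,1.5251257463981958
16.5,1.523288379886353
17,1.5214510133745103
17.5,1.5196136468626678
18,1.517776280350825
18.5,1.5159389138389823
19,1.5141015473271395
19.5,1.5122641808152968
20,1.510426814303454
20.5,1.5085894477916115
21,1.5067520812797688
21.5,1.504914714767926
22,1.5030773482560835
22.5,1.5012399817442408
23,1.499402615232398
23.5,1.4969448448597396
24,1.4834669415387007
24.5,1.4555689266997995
25,1.413948774085348
25.5,1.3596421152790068
26,1.2939957941773255
26.5,1.2186337877472377
27,1.1354163549705856
27.5,1.0463934413196294
28,0.95375350572055284
28.5,0.85976904735326098
29,0.76674018814491396
29.5,0.6769377115770534
30,0.59254696841710985
30.5,0.51561403504308612
31,0.44799545085885234
31.5,0.39131276944595894
32,0.34691303592038142
32.5,0.31583615355829603
33,0.29878992988915509
33.5,0.2961334004638011
34,0.30786882218947315
34.5,0.3336425126244153
35,0.37275449229890573
35.5,0.42417666941487103
36,0.48657909555725531
36.5,0.55836362252486149
37,0.63770410893944685
37.5,0.72259216536751958
38,0.81088729219362365
38.5,0.90037015868177295
39,0.98879769709942111
39.5,1.0739586442226028
40,1.1537281549367775
40.5,1.2261201390978114
41,1.289336032580509
41.5,1.3418088049545673
42,1.3822411271441037
42.5,1.4096367696795702
43,1.4233244720281681
43.5,1.4240705882468474
44,1.4222332217350047
44.5,1.4203958552231619
45,1.4185584887113192
45.5,1.4167211221994764
46,1.4148837556876337
46.5,1.4130463891757912
47,1.4112090226639484
47.5,1.4093716561521057
48,1.4075342896402629
48.5,1.4056969231284202
49,1.4038595566165775
49.5,1.4020221901047349
50,1.4001848235928922
50.5,1.3983474570810497
51,1.3965100905692069
51.5,1.3946727240573642
52,1.3928353575455215
52.5,1.3909979910336787
53,1.3891606245218362
53.5,1.3873232580099935
54,1.3854858914981507
54.5,1.383648524986308
55,1.3818111584744652
55.5,1.3799737919626225
56,1.37813642545078
56.5,1.3762990589389372
57,1.3744616924270945
57.5,1.3705663079255717
58,1.3611677711244048
58.5,1.3463609734748667
59,1.3263917129851566
59.5,1.3015942351734759
60,1.2723852256972339
60.5,1.239256395534948
61,1.2027657905521694
61.5,1.1635279789658979
62,1.1222032891946425
62.5,1.0794862865228527
63,1.0360936896515263
63.5,0.99275193734171152
64,0.95018462083590827
64.5,0.90909999947918751
65,0.87017881493720894
65.5,0.83406261366739076
66,0.80134277795144793
66.5,0.77255045301373282
67,0.7481475417604353
67.5,0.72851891976482008
68,0.71396600162794455
68.5,0.70470176614132596
69,0.70084732218336487
69.5,0.70243007044056405
70,0.70938348832520726
70.5,0.72154853734466873
71,0.73867666415093325
71.5,0.76043433904635616
72,0.78640904931605871
72.5,0.81611663985216465
73,0.84900987055663035
73.5,0.88448803934954567
74,0.9219075016191991
74.5,0.96059290193242663
75,0.99984892203020903
75.5,1.0389723407589913
76,1.0772641967681102
76.5,1.1140418436114052
77,1.1486506893371535
77.5,1.1804754186824546
78,1.2089505054918832
78.5,1.2335698357816711
79,1.2538952777394028
79.5,1.2695640536023485
80,1.280294789464933
80.5,1.2858921422557057
81,1.2862680998586449
81.5,1.2844307333468021
82,1.2825933668349596
82.5,1.2807560003231169
83,1.2789186338112741
83.5,1.2770812672994314
84,1.2752439007875886
84.5,1.2734065342757459
85,1.2715691677639034
85.5,1.2697318012520606
86,1.2678944347402179
86.5,1.2660570682283752
87,1.2642197017165324
87.5,1.2623823352046897
88,1.2605449686928472
88.5,1.2587076021810044
89,1.2568702356691617
89.5,1.2550328691573189
90,1.2531955026454762
90.5,1.2513581361336334
91,1.2495207696217909
91.5,1.2476834031099482
92,1.2458460365981054
92.5,1.2440086700862627
93,1.24217130357442
93.5,1.2403339370625772
94,1.2384965705507347
94.5,1.2366592040388922
95,1.2348218375270492
95.5,1.2329844710152067
96,1.231147104503364
96.5,1.2293097379915212
97,1.2274723714796785
97.5,1.225635004967836
98,1.2237976384559932
98.5,1.2219602719441505
99,1.2201229054323077
99.5,1.218285538920465
100,1.2164481724086222
100.5,1.2146108058967797
100.75,1.2136921226408581
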