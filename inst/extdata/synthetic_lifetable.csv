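Age,qx
50,0.0036195601866777505
51,0.0039196732304149773
52,0.0042486027341281929
53,0.0046091046467845453
54,0.0050041962759729275
55,0.0054371806257597077
56,0.0059116729098837029
57,0.0064316294159956211
58,0.0070013789068624765
59,0.0076256567543314668
60,0.0083096420111181679
61,0.0090589976337630551
62,0.0098799140769699756
63,0.0107791564844170740
64,0.0117641157033449018
65,0.0128428633489325872
66,0.0140242111386476020
67,0.0153177747051596036
68,0.0167340420775474730
69,0.0182844469926144448
70,0.0199814471590105125
71,0.0218386075440092364
72,0.0238706886831837606
73,0.0260937399233475142
74,0.0285251973948261739
75,0.0311839863656122596
76,0.0340906274516716845
77,0.0372673459382801830
78,0.0407381831995534682
79,0.0445291088792119094
80,0.0486681321061004368
81,0.0531854095532816595
82,0.0581133475991071347
83,0.0634866952016107655
84,0.0693426233427872907
85,0.0757207860262608667
86,0.0826633568112292716
87,0.0902150337305497318
88,0.0984230041685466572
89,0.1073368598677225672
90,0.1170084507049033995
91,0.1274916642503819419
92,0.1388421164386208773
93,0.1511167369978243524
94,0.1643732316976775909
95,0.1786694021040616809
96,0.1940623025436387650
97,0.2106072135980203708
98,0.2283564119441822138
99,0.2473577180784060081
100,0.2676528068188351872
101,0.2892752709590150628
102,0.3122484365827155051
103,0.3365829399267401545
104,0.3622740908675989857
105,0.3892990676168650577
106,0.4176140113847174318
107,0.4471511186669462345
108,0.4778158620236875320
109,0.5094845066785883558
110,0.5420021280040234757
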