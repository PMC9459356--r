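time,event,arm
1.322695226936110302,1,A
1.071166569342679287,1,B
2.401894816597801352,1,A
4.744467541359841611,1,A
0.311189839790213751,1,B
1.425553209421840606,1,A
0.995045843764333804,1,B
0.582927628557569522,1,A
1.528221319092915698,1,A
1.948756748768252667,1,A
1.460977986781261784,1,B
1.274405790192567389,1,A
1.907924876550179505,1,B
0.791827475918888246,1,B
0.961621292724649468,1,A
4.724897841690108180,0,A
0.667565005865838335,1,B
1.458859221464206435,1,B
0.370946125198362897,1,A
0.161206245721499830,1,B
0.264674927831916762,1,B
0.761030212506423775,1,B
0.277858836965795941,1,A
0.792005709967180227,1,B
0.377255309972855224,1,A
3.001003665700233913,1,B
1.438943563451722696,1,A
0.839136316328135012,1,B
4.933805520646274090,0,A
0.074958254044378614,1,B
1.296335483705103542,1,B
2.089992114880653062,1,A
0.378191010250972848,1,A
0.258334855254367113,1,A
1.732746428752453882,1,A
1.566117090866023576,1,B
1.937653777302252855,1,A
1.307324504265108267,1,B
0.459558006069929192,1,B
3.084960827413457451,1,B
0.533651467716556471,1,B
4.006332489993654100,1,A
0.885148124925098645,1,B
0.244898434859182473,1,B
0.418487760500458883,1,B
0.249193767552021050,1,B
1.325961174171114365,1,A
1.873136010967623610,1,A
0.539961671077154093,1,A
0.889600966448005126,1,A
4.553652501665055752,0,A
2.096097122259055645,1,B
0.814214531326586832,1,A
2.447136228612255771,1,B
0.066752092643645414,1,B
1.080499119091250293,1,B
0.773408332103236895,1,A
0.111735685037957166,1,A
2.020346570461013957,1,A
0.168416206327565598,1,B
0.702163609866144900,1,A
0.492286867498422820,1,B
0.125996859478769679,1,B
0.586285692814242920,1,A
2.188348131746204572,1,B
3.520247914306505077,1,A
1.179409003031550718,1,A
0.499800199177236726,1,A
0.680590583915023695,1,B
0.563504953742550052,1,A
0.827714731493551237,1,B
0.325077119190830377,1,A
0.191644805556147463,1,A
1.492422627143615843,1,A
3.570613831797214921,1,B
0.410762361171438384,1,A
2.070411417289537592,1,B
0.204051865504573299,1,B
0.511030821736897845,1,A
0.911663340838771763,1,B
0.414091972250337059,1,A
0.124495393279216215,1,B
1.001878240901007189,1,A
1.514264432616585943,1,B
0.370734234460565637,1,B
0.503991810008891927,1,A
0.119927731788397399,1,A
2.082770567078118695,1,A
1.748717321788970880,1,B
0.925106672820659170,1,B
0.301098365420645275,1,A
0.821500079537507255,1,A
0.711136452490686910,1,B
0.450763496390801599,1,A
0.580727945319202132,1,A
0.337404158127228848,1,A
0.432384246449505960,1,A
0.288313079120289917,1,B
2.684658922836117512,1,B
0.057387842635206146,1,A
0.340219791277808270,1,B
0.609466273716371854,1,B
0.284181023895799301,1,A
1.779638251793179471,1,B
1.675595505036213240,1,A
1.758397115361010066,1,B
0.260057912677458258,1,A
0.728880169834433378,1,B
0.719622417393437019,1,A
1.269312233930195433,1,A
1.783680163601218283,1,B
0.118616586664440221,1,B
0.139976240349827252,1,A
1.721284796623181457,1,B
0.683410884896202941,1,A
0.893375765472356087,1,A
2.101462370388639478,1,B
0.885311664699588996,1,A
0.722028451946998051,1,B
0.881095317412289969,1,B
0.571056219181042324,1,A
0.976110711535108089,1,B
1.227317836931380413,1,A
0.886758276220961594,1,A
0.012290434106288958,1,A
0.961691000517765127,1,B
1.163282610004820361,1,A
4.866796877700835466,0,A
0.547694034101130711,1,A
0.398830256583844023,1,B
4.014559435890987515,0,A
0.967439386927398282,1,A
0.201021209597198880,1,A
2.962772500944236942,1,A
0.808399930671075517,1,B
0.905452269338585247,1,B
1.063318973458329708,1,A
1.535856707571205959,1,B
1.863041721318144273,1,A
1.048211598656720644,1,A
0.920345501364361440,1,B
1.222069361635936380,1,B
1.313716052173540261,1,B
1.470631495166698111,1,B
1.159411459657143872,1,A
0.794181199942772365,1,A
0.431811762213351491,1,B
2.047554853022180321,1,B
0.723960363434983156,1,A
0.492542395268040167,1,A
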