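phase,grn,N,L,n_D,l_r,l_o,l_c,D,H,gamma
1,Enveloping Layer,503,2711,0.862823,0.0217632,0.977868,0.00036887,5.38966203,1.41985,2.20982081
1,Primordial Germ cells,259,954,0.826255,0.0303983,0.964361,0.00524109,3.68339768,1.235732,2.17165245
1,Blastomeres,511,1270,0.882583,0.313386,0.677953,0.00866142,2.4853229,1.423221,2.23017674
2,Enveloping Layer,529,1743,0.865785,0.35743,0.627653,0.0149168,3.29489603,1.447612,2.22345159
2,Primordial Germ cells,341,641,0.859238,0.218409,0.76131,0.0202808,1.8797654,1.273093,2.41007383
2,Ectoderm,451,1130,0.873614,0.311504,0.680531,0.0079646,2.50554324,1.399564,2.23809286
2,Other Mesendoderm,473,843,0.892178,0.213523,0.772242,0.0142349,1.78224101,1.306278,2.2194016
2,Other Axial Mesoderm,480,1257,0.85625,0.358791,0.633254,0.00795545,2.61875,1.42566,2.25256201
3,Enveloping Layer,584,1156,0.868151,0.262976,0.723183,0.0138408,1.97945205,1.338638,2.39407086
3,Primordial Germ cells,397,1208,0.798489,0.234272,0.754139,0.0115894,3.04282116,1.318965,2.26719939
3,Ectoderm,436,1238,0.866973,0.214863,0.775444,0.00969305,2.83944954,1.413963,2.20445767
3,Paraxial Mesoderm,457,814,0.899344,0.14742,0.837838,0.014742,1.78118162,1.288964,2.14650461
3,Other Mesendoderm,477,1009,0.890985,0.278494,0.705649,0.0158573,2.11530398,1.379758,2.35570319
3,Notochord,447,749,0.87472,0.245661,0.735648,0.0186916,1.67561521,1.272235,2.20355315
3,Prechordal Plate,454,657,0.914097,0.161339,0.83105,0.00761035,1.44713656,1.230409,2.05510966
4,Enveloping Layer,544,2302,0.841912,0.0438749,0.953519,0.00260643,4.23161765,1.290836,2.29417041
4,Primordial Germ cells,324,1402,0.746914,0.0763195,0.914408,0.00927247,4.32716049,1.227669,2.3672417
4,Spinal Cord,337,699,0.762611,0.374821,0.579399,0.0457797,2.07418398,1.266472,2.54612079
4,Diencephalon,319,639,0.821317,0.261346,0.707355,0.0312989,2.0031348,1.28039,2.28520814
4,Optic Cup,270,793,0.811111,0.32913,0.655738,0.0151324,2.93703704,1.381626,2.18875359
4,midbrain + neural crest,284,554,0.799296,0.279783,0.691336,0.0288809,1.95070423,1.24442,2.44389368
4,Hindbrain R3,266,1058,0.736842,0.113422,0.881853,0.0047259,3.97744361,1.292785,2.29394744
4,Hindbrain R4 + 5 + 6,316,726,0.803797,0.34573,0.628099,0.0261708,2.29746835,1.310362,2.46964724
4,Telencephalon,283,1091,0.75265,0.159487,0.835014,0.00549954,3.85512367,1.347187,2.26629625
4,Epidermis,365,757,0.873973,0.245707,0.742404,0.011889,2.0739726,1.356486,2.15727157
4,Neural Plate Border,333,1092,0.777778,0.391026,0.60348,0.00549451,3.27927928,1.37895,2.19454937
4,Placode Adeno + Lens + Trigeminal,325,1534,0.710769,0.507823,0.481095,0.0110821,4.72,1.349381,2.23508351
4,Placode Epibranchial + Otic,356,889,0.772472,0.419573,0.55793,0.0224972,2.49719101,1.319675,2.36222696
4,Placode Olfactory,346,1432,0.702312,0.369413,0.618017,0.0125698,4.13872832,1.276427,2.41107073
4,Tailbud,299,528,0.879599,0.179924,0.797348,0.0227273,1.76588629,1.28214,2.19869675
4,Adaxial Cells,332,498,0.873494,0.154618,0.825301,0.0200803,1.5,1.217218,2.38408741
4,Somites,346,1780,0.739884,0.441011,0.553371,0.00561798,5.14450867,1.37596,2.23017205
4,Hematopoietic ICM,283,684,0.756184,0.406433,0.562865,0.0307018,2.41696113,1.276187,2.41166907
4,Hematopoietic RBI + Pronephros,349,1232,0.679083,0.468344,0.511364,0.0202922,3.53008596,1.271202,2.46907124
4,Endoderm Pharyngeal,392,1694,0.714286,0.603306,0.374262,0.0224321,4.32142857,1.355556,2.31163522
4,Endoderm Pancreatic + Intestinal,394,1009,0.779188,0.453915,0.508424,0.037661,2.56091371,1.324395,2.39073542
4,Heart Primordium,342,1770,0.72807,0.173446,0.824859,0.00169492,5.1754386,1.371556,2.22238996
4,Cephalic Mesoderm,327,2028,0.715596,0.231262,0.764793,0.00394477,6.20183486,1.330649,2.17679476
4,Prechordal Plate,340,465,0.888235,0.0989247,0.87957,0.0215054,1.36764706,1.174788,2.28500226
4,Notochord,356,1427,0.803371,0.170287,0.82691,0.00280308,4.00842697,1.362417,2.19148314
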