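{"W1":[-0.149762170691513,-0.907648266201092,0.153982327415436,0.263840194458671,0.385021707086711,-0.0893626324395402,-0.948540360182456,0.14958348382471,-0.300331815566048,-0.241290550420267,0.017209000771712,0.0937558243560537,0.166687799152111,-0.105287324275849,-1.01406788296691,-0.544884518512145,0.392722563839259,1.24322695292551,-0.202532847930488,-0.196863002069136,0.114739779067895,0.156025189321797,1.18673358490294,0.00655870457240909,0.284128768682265,0.929995833796012,-0.174578490902571,-0.196387531926572,0.0977555002651225,0.157256959188823,0.97146754260201,0.0424706366954581,-0.364976897058929,-0.850176399538252,0.0833757570835768,0.414432629831462,-0.261957648343969,-0.156539937415668,-1.47057183643334,-0.241431421636523,-0.274750937656349,-1.40362088578126,0.153029196631468,0.138757865972135,-0.102861410974611,-0.168175734009705,-0.941764344186531,0.431393929257676,0.0089242169319179,-0.441978805960078,-0.320658439306776,0.492757118221911,-0.0497551967798312,-0.160383580867848,-0.0170592098094691,-0.0801836416363459,-0.44077675423748,-1.7673903601825,0.333334770340958,0.127686590693408,-0.0982901568695548,-0.191845826670758,-1.14291614308083,0.237198924451905],"b1":[0.704051860036447,0.784708046738187,-1.02123365384419,-0.650905214816642,0.828792361913561,0.779989736938836,0.589401154842029,1.21157717988087],"w2":[-1.21974041774778,-1.27988532606069,1.01869534494363,1.42483621107937,-0.94353930955572,-1.40106670752022,-0.61014018931899,-1.33752020692229],"b2":-0.428618381693593,"centre":[1564.70153211636,50.798876026108,22.8153969666588,0.63286219669246,1.05121720924049,0.0581856651467457,10.1347617284498,0.27549405758797],"scale":[649.576363212231,21.0070264391748,17.7861342472127,0.0672500594067444,0.0427568208657762,0.00904006017905881,3.71062722058543,0.264696142292795],"feature_names":["density_per_mm2","mean_area_um2","sd_area_um2","mean_ecc","mean_h","sd_h","mean_nn_um","frac_large"],"hidden":8,"pool":"lse","pool_r":4,"epochs":400,"lr":0.01,"l2":0.0001,"seed":42,"d":8}
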