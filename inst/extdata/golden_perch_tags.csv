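fish_id,capture_river,tag_year,length_mm,weight_g,angler_removed
M01,Murray,2007,498,1685,FALSE
M02,Murray,2007,390,1000,FALSE
M03,Murray,2007,365,800,FALSE
M04,Murray,2007,420,1500,FALSE
M05,Murray,2007,520,2790,FALSE
M06,Murray,2007,490,2400,FALSE
M07,Murray,2007,410,1100,FALSE
M08,Murray,2007,500,2480,FALSE
M09,Murray,2007,395,1010,FALSE
M10,Murray,2007,424,1320,FALSE
M11,Murray,2007,497,1975,FALSE
M12,Murray,2007,465,1650,FALSE
M13,Murray,2007,580,3400,FALSE
M14,Murray,2007,363,750,FALSE
M15,Murray,2007,530,2900,FALSE
M16,Murray,2008,410,1082,FALSE
M17,Murray,2008,366,745,FALSE
M18,Murray,2008,415,1193,FALSE
M19,Murray,2008,350,540,FALSE
M20,Murray,2008,435,1337,FALSE
M21,Murray,2008,424,1518,FALSE
M22,Murray,2008,450,1309,FALSE
M23,Murray,2008,430,1582,FALSE
M24,Murray,2008,470,2270,FALSE
M25,Murray,2008,510,1963,FALSE
M26,Murray,2008,415,1435,FALSE
M27,Murray,2008,375,711,FALSE
M28,Murray,2008,380,806,FALSE
M29,Murray,2008,410,1435,FALSE
M30,Murray,2009,320,510,FALSE
M31,Murray,2009,450,1584,FALSE
M32,Murray,2009,390,954,FALSE
M33,Murray,2009,470,1450,FALSE
M34,Murray,2009,400,1068,FALSE
M35,Murray,2009,420,1184,FALSE
M36,Murray,2009,505,1646,FALSE
M37,Murray,2009,505,2280,FALSE
M38,Murray,2009,400,860,FALSE
M39,Murray,2009,425,1168,FALSE
M40,Murray,2009,540,2938,FALSE
M41,Murray,2009,520,2668,FALSE
M42,Murray,2009,360,830,FALSE
G01,Goulburn,2007,400,1030,FALSE
G02,Goulburn,2007,415,1270,FALSE
G03,Goulburn,2007,460,1700,FALSE
G04,Goulburn,2007,520,2590,FALSE
G05,Goulburn,2007,485,2150,FALSE
G06,Goulburn,2007,435,1860,TRUE
G07,Goulburn,2007,505,2480,FALSE
G08,Goulburn,2007,405,1070,FALSE
G09,Goulburn,2007,350,730,FALSE
G10,Goulburn,2007,470,1960,FALSE
G11,Goulburn,2007,495,2430,FALSE
G12,Goulburn,2007,342,700,FALSE
G13,Goulburn,2008,340,1026,FALSE
G14,Goulburn,2008,360,610,FALSE
G15,Goulburn,2008,460,2400,FALSE
G16,Goulburn,2008,365,965,FALSE
G17,Goulburn,2008,445,2200,FALSE
G18,Goulburn,2008,440,1260,TRUE
G19,Goulburn,2008,435,1480,FALSE
G20,Goulburn,2008,342,615,FALSE
G21,Goulburn,2008,315,510,FALSE
G22,Goulburn,2008,320,1120,FALSE
G23,Goulburn,2008,370,1125,TRUE
G24,Goulburn,2009,370,910,FALSE
G25,Goulburn,2009,420,1310,FALSE
G26,Goulburn,2009,340,590,FALSE
G27,Goulburn,2009,500,1858,FALSE
G28,Goulburn,2009,430,1504,FALSE
G29,Goulburn,2009,500,2062,FALSE
G30,Goulburn,2009,465,2466,FALSE
G31,Goulburn,2009,320,580,FALSE
G32,Goulburn,2009,360,610,FALSE
G33,Goulburn,2009,480,2254,FALSE
G34,Goulburn,2009,360,815,FALSE
G35,Goulburn,2009,360,798,FALSE
G36,Goulburn,2009,450,1710,FALSE
G37,Goulburn,2009,470,1845,FALSE
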