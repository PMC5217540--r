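code,base_category,subgroup,kind,intensity_class
137..,,Tobacco consumption (parent),parent,
1371.,NEVER,Never smoked tobacco,status,
137l.,NEVER,Never smoked tobacco,status,
137F.,EX,Ex smoker (general),status,
137K.,EX,Ex smoker (general),status,
137S.,EX,Ex smoker (general),status,
1377.,EX,Ex smoker intensity prior to quitting,intensity,trivial
1378.,EX,Ex smoker intensity prior to quitting,intensity,light
1379.,EX,Ex smoker intensity prior to quitting,intensity,medium
137A.,EX,Ex smoker intensity prior to quitting,intensity,heavy
137B.,EX,Ex smoker intensity prior to quitting,intensity,very_heavy
137O.,EX,Ex smoker type (non cigarette),status,
137N.,EX,Ex smoker type (non cigarette),status,
137j.,EX,Ex smoker (cigarette only),status,
137T.,EX,Ex smoker admin,cessation_admin,
137R.,SMOKER,Smoker (general),status,
137C.,SMOKER,Smoker (general),status,
137P.,SMOKER,Smoker (general),status,
1372.,SMOKER,Smoking intensity,intensity,trivial
1373.,SMOKER,Smoking intensity,intensity,light
1374.,SMOKER,Smoking intensity,intensity,medium
1375.,SMOKER,Smoking intensity,intensity,heavy
1376.,SMOKER,Smoking intensity,intensity,very_heavy
137G.,SMOKER,Smokers unwilling to quit,status,
137Q.,SMOKER,Smoker type (non cigarette),status,
137H.,SMOKER,Smoker type (non cigarette),status,
137J.,SMOKER,Smoker type (cigarette only),status,
137V.,SMOKER,Smoking Value,status,
E251.,SMOKER,Nicotine dependence,status,
E2510,SMOKER,Nicotine dependence,status,
T4023,SMOKER,Toxicity,status,
du331,SMOKER,Nicotine Replacement Therapy,therapy,
du332,SMOKER,Nicotine Replacement Therapy,therapy,
du333,SMOKER,Nicotine Replacement Therapy,therapy,
du41.,SMOKER,Therapy,therapy,
du42.,SMOKER,Therapy,therapy,
8H7i.,SMOKER,Passive cessation,cessation_admin,
8IEM.,SMOKER,Passive cessation,cessation_admin,
137e.,SMOKER,Active Cessation,cessation_admin,
137f.,SMOKER,Active Cessation,cessation_admin,
9N2k.,SMOKER,Administrative,cessation_admin,
9N4M.,SMOKER,Administrative,cessation_admin,
6791.,SMOKER,Advice,advice,
8CAL.,SMOKER,Advice,advice,
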