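arm,name,incidence,mgmt_cost,disutility,kind
serplulimab,anemia,0.1081,6.96,0.085,one_off
serplulimab,hyperbilirubinemia,0.0676,76.16,0,one_off
serplulimab,impaired_liver_function,0.0541,76.16,0,one_off
serplulimab,alt_elevated,0.0135,76.16,0,one_off
serplulimab,lung_infection,0.0270,88.85,0.195,one_off
serplulimab,neutropenia,0.0405,62.62,0.0607,one_off
serplulimab,leukopenia,0.0270,62.62,0.0607,one_off
serplulimab,diarrhea,0.0270,2.95,0.07,one_off
serplulimab,creatine_kinase_elevated,0.0270,3.28,0,one_off
serplulimab,hypertension,0.0270,0.18,0.04,periodic
regorafenib,hyperbilirubinemia,0.0600,37.92,0,one_off
regorafenib,alt_elevated,0.0700,37.92,0,one_off
regorafenib,ast_elevated,0.0600,37.92,0,one_off
regorafenib,neutropenia,0.0200,84.93,0.0607,one_off
regorafenib,leukopenia,0.0200,26.48,0.0607,one_off
regorafenib,thrombocytopenia,0.0300,2139.77,0.19,one_off
regorafenib,diarrhea,0.0100,12.04,0.07,one_off
regorafenib,hypertension,0.1100,0.18,0.04,periodic
regorafenib,hand_foot_skin_reaction,0.1600,16.18,0.116,one_off
regorafenib,maculopapular_rash,0.0400,17.63,0.03248,one_off
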