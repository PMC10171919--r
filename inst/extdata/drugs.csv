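arm,unit_price,vial_mg,mg_per_kg,weight_kg,admins_per_cycle,max_cycles,daily_doses_per_cycle
serplulimab,828.92,100,3,65,2,26,NA
regorafenib,102.34,NA,NA,NA,NA,NA,21
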