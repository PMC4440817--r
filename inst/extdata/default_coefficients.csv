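"enterprise","zone","revenue_per_ha","cost_per_ha","emissions_per_ha","sequestration_per_ha","n_leach_per_ha","p_loss_per_ha","feasible"
"Dairy","Plains",6500,3600,10,0,45,1.2,TRUE
"Dairy","Foothills",2650,2110,10,0,40,1.1,TRUE
"Dairy","Hills",0,0,0,0,0,0,FALSE
"SheepBeef","Plains",1450,600,4,0,12,0.9,TRUE
"SheepBeef","Foothills",1100,540,4,0,10,0.8,TRUE
"SheepBeef","Hills",900,500,4,0,8,0.6,TRUE
"Forestry","Plains",1050,450,0,7,3,0.2,TRUE
"Forestry","Foothills",950,420,0,7,3,0.2,TRUE
"Forestry","Hills",900,400,0,7,3,0.2,TRUE
"CarbonForestry","Plains",0,120,0,12,2,0.15,TRUE
"CarbonForestry","Foothills",0,120,0,12,2,0.15,TRUE
"CarbonForestry","Hills",0,120,0,12,2,0.15,TRUE
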