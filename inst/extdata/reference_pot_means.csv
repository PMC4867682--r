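# Treatment means of the source barley pot experiment (published summary
# values; fixed inputs for worked-example consistency checks).
# units: dm g/kg soil; p_conc mg P/g DM; uptake mg P/kg soil; percentages %
soil,treatment,labeling,dm_g_per_kg,p_conc_mg_per_g,uptake_mg_per_kg,pdf_fertilizer_pct,recovery_pct,rae_pct
unlimed,NoP,indirect,3.5,1.6,5.7,,,
unlimed,MinP,indirect,5.2,1.9,10.2,42.4,14.4,100
unlimed,Manure,indirect,4.1,1.7,7.0,40.2,8.8,60.9
unlimed,FishSludge,indirect,4.0,1.9,7.5,29.0,6.9,47.8
unlimed,MeatBoneMeal,indirect,3.5,1.8,6.4,11.2,2.3,16.0
unlimed,WoodAsh,indirect,3.7,1.9,7.1,23.6,5.6,38.7
unlimed,MinPdir,direct,5.0,2.1,10.3,36.9,12.7,
limed,NoP,indirect,3.5,1.8,6.4,,,
limed,MinP,indirect,5.0,2.2,10.8,45.1,16.3,100
limed,Manure,indirect,4.6,1.8,8.3,41.0,10.7,65.7
limed,FishSludge,indirect,4.5,1.9,8.7,28.6,7.9,48.6
limed,MeatBoneMeal,indirect,3.7,1.9,7.0,18.8,4.4,26.9
limed,WoodAsh,indirect,3.9,1.9,7.6,28.1,7.1,43.8
limed,MinPdir,direct,4.9,2.3,11.2,33.5,12.5,
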