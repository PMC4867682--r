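# Treatment means of the source soil-fertilizer incubation (published
# summary values; fixed inputs for worked-example consistency checks).
# units: c_p mg P/L; e1min, resin P, pmic mg P/kg soil; pdff %
soil,treatment,ph,c_p_mg_per_l,m,n,e1min_mg_per_kg,resin_p_day7,resin_p_day21,pdff_resin_day7_pct,pdff_resin_day21_pct,pmic_day7,pmic_day21
unlimed,NoP,5.51,0.09,0.27,0.40,3.3,12.5,10.1,,,2.8,6.2
unlimed,MinP,5.49,0.15,0.32,0.38,4.8,21.6,25.2,38,52,3.7,3.6
unlimed,Manure,5.58,0.13,0.29,0.39,4.6,23.7,13.9,32,38,6.4,9.7
unlimed,FishSludge,5.45,0.12,0.27,0.39,4.4,19.1,16.6,37,30,5.8,3.0
unlimed,MeatBoneMeal,5.44,0.12,0.27,0.39,4.5,21.5,10.1,25,19,,9.9
unlimed,WoodAsh,5.73,0.12,0.26,0.39,4.4,19.1,13.9,30,40,9.2,5.0
limed,NoP,6.25,0.08,0.23,0.37,3.5,10.3,11.8,,,9.1,6.8
limed,MinP,6.23,0.15,0.27,0.35,5.4,16.7,23.4,43,41,18.8,6.1
limed,Manure,6.30,0.13,0.24,0.35,5.3,18.8,16.9,49,40,14.7,15.1
limed,FishSludge,6.17,0.10,0.24,0.37,4.2,9.7,13.2,35,24,14.8,11.9
limed,MeatBoneMeal,6.15,0.09,0.22,0.37,4.2,12.5,14.2,29,12,7.0,6.7
limed,WoodAsh,6.45,0.14,0.22,0.34,6.1,13.7,15.5,40,43,13.1,9.8
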