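# Rootability-index rules for maize, one breakpoint per row.
# For each factor the rule is the piecewise-linear interpolation of ri (%)
# against value, constant beyond the outer breakpoints. The breakpoint with
# ri = 20 is the threshold value of the factor. Derived variables:
# f_bd = bd - (1.6 - 0.0035*clay); d_sand/d_clay = increase from the interval
# above; f_exch_al = 100*exch_al/cec.
factor,variable,unit,value,ri
porosity_vmc_sat,vmc_sat,v%,0,0
porosity_vmc_sat,vmc_sat,v%,27.5,0
porosity_vmc_sat,vmc_sat,v%,30,20
porosity_vmc_sat,vmc_sat,v%,40,100
porosity_vmc_sat,vmc_sat,v%,100,100
porosity_f_bd,f_bd,kg/dm3,0,100
porosity_f_bd,f_bd,kg/dm3,0.24,20
porosity_f_bd,f_bd,kg/dm3,0.3,0
volume_crsvol,cf,v%,0,100
volume_crsvol,cf,v%,80,100
volume_crsvol,cf,v%,88,20
volume_crsvol,cf,v%,90,0
volume_crsvol,cf,v%,100,0
texture_sand,sand,g/100 g,0,100
texture_sand,sand,g/100 g,95,100
texture_sand,sand,g/100 g,99,20
texture_sand,sand,g/100 g,100,0
texture_f_sand,d_sand,g/100 g,0,100
texture_f_sand,d_sand,g/100 g,30,100
texture_f_sand,d_sand,g/100 g,50,20
texture_f_sand,d_sand,g/100 g,55,0
texture_f_sand,d_sand,g/100 g,100,0
texture_f_clay,d_clay,g/100 g,0,100
texture_f_clay,d_clay,g/100 g,30,100
texture_f_clay,d_clay,g/100 g,50,20
texture_f_clay,d_clay,g/100 g,55,0
texture_f_clay,d_clay,g/100 g,100,0
induration_caco3,caco3,g/kg,0,100
induration_caco3,caco3,g/kg,150,100
induration_caco3,caco3,g/kg,400,20
induration_caco3,caco3,g/kg,450,0
induration_caco3,caco3,g/kg,1000,0
induration_caso4,caso4,g/kg,0,100
induration_caso4,caso4,g/kg,50,100
induration_caso4,caso4,g/kg,300,20
induration_caso4,caso4,g/kg,350,0
induration_caso4,caso4,g/kg,1000,0
acidity_ph,ph,-,1,0
acidity_ph,ph,-,3.63,0
acidity_ph,ph,-,4,20
acidity_ph,ph,-,5.5,100
acidity_ph,ph,-,12,100
alkalinity_ph,ph,-,1,100
alkalinity_ph,ph,-,7.8,100
alkalinity_ph,ph,-,8.8,20
alkalinity_ph,ph,-,9.05,0
alkalinity_ph,ph,-,12,0
salinity_ec,ec,dS/m,0,100
salinity_ec,ec,dS/m,1.5,100
salinity_ec,ec,dS/m,5.7,20
salinity_ec,ec,dS/m,6.75,0
sodicity_exch_na,exch_na,cmolc/kg,0,100
sodicity_exch_na,exch_na,cmolc/kg,1,100
sodicity_exch_na,exch_na,cmolc/kg,4.2,20
sodicity_exch_na,exch_na,cmolc/kg,5,0
toxicity_exch_al,exch_al,cmolc/kg,0,100
toxicity_exch_al,exch_al,cmolc/kg,2.5,100
toxicity_exch_al,exch_al,cmolc/kg,5.7,20
toxicity_exch_al,exch_al,cmolc/kg,6.5,0
toxicity_f_exch_al,f_exch_al,%,0,100
toxicity_f_exch_al,f_exch_al,%,35,100
toxicity_f_exch_al,f_exch_al,%,75,20
toxicity_f_exch_al,f_exch_al,%,85,0
toxicity_f_exch_al,f_exch_al,%,100,0
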